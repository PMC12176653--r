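# Shared fixtures are built once per test run and cached; everything is
# generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 8 murine families x 3, geometric jitter 0.1, no pixel noise
cohort_small <- function() fixture("cohort_small", function()
  generate_cohort(setNames(rep(3L, 8), murine_families()),
                  jitter = 0.1, seed = 42, noise_level = 0))

profile_small <- function() fixture("profile_small", function()
  profile_cohort(cohort_small()))

# draw a capsule/disk mask directly (analytic fixture, no generator)
capsule_mask <- function(n, x1, y1, x2, y2, r) {
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  Y <- matrix(seq_len(n), n, n)
  vx <- x2 - x1; vy <- y2 - y1
  l2 <- max(vx^2 + vy^2, 1e-12)
  tt <- pmin(pmax(((X - x1) * vx + (Y - y1) * vy) / l2, 0), 1)
  (X - (x1 + tt * vx))^2 + (Y - (y1 + tt * vy))^2 <= r^2
}

disk_mask <- function(n, cx, cy, r) capsule_mask(n, cx, cy, cx, cy, r)

as_seg_mask <- function(m, ps = 1) {
  structure(list(mask = m, pixel_size_um = ps, n_components = 1L,
                 largest_component_only = TRUE, threshold = 0.5,
                 blank = FALSE), class = "segmentation_mask")
}

# mean silhouette width of a labelling on a feature matrix (test oracle)
mean_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  labels <- as.character(labels)
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
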