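#' Median-of-ratios library-size factors
#'
#' For each sample, the size factor is the median over genes of the ratio
#' of its count to the gene's geometric mean across samples, computed over
#' genes with strictly positive geometric mean.
#'
#' @param counts genes x samples matrix of nonnegative integers.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  zero_s <- colSums(counts) == 0
  if (any(zero_s))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero_s] %||% which(zero_s), collapse = ", "))
  lg <- rowMeans(log(counts + 0L), na.rm = FALSE)
  use <- is.finite(lg)  # genes with no zero anywhere
  if (!any(use)) stop("no gene has a positive geometric mean")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
    median(exp(log(cnt) - lg[use])))
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' One-vs-rest negative binomial differential expression
#'
#' Per gene, fits the NB log-linear model
#' `count ~ target_indicator + offset(log size factor)` with gene-wise
#' maximum-likelihood dispersion (floored), and tests the indicator
#' coefficient with a Wald test. P-values are Benjamini-Hochberg adjusted
#' across tested genes. Genes with all-zero counts are excluded and
#' recorded.
#'
#' @param counts genes x samples nonnegative integer matrix.
#' @param labels per-sample phenotype labels.
#' @param target_phenotype the phenotype contrasted against all others.
#' @param sf size factors; computed by [size_factors()] when `NULL`.
#' @param dispersion_floor smallest admissible NB dispersion (alpha); the
#'   fallback fit when per-gene ML estimation fails.
#' @return a `de_result` data frame: `gene`, `base_mean`,
#'   `log2_fold_change`, `wald_statistic`, `p_value`, `p_adjusted`,
#'   `dispersion`; attributes `contrast`, `size_factors`,
#'   `excluded_genes`.
#' @export
phenotype_de <- function(counts, labels, target_phenotype, sf = NULL,
                         dispersion_floor = 1e-4) {
  counts <- as.matrix(counts)
  labels <- as.character(labels)
  if (ncol(counts) != length(labels)) stop("labels must align with samples")
  if (!target_phenotype %in% labels) stop("unknown phenotype: ",
                                          target_phenotype)
  grp <- factor(labels == target_phenotype, levels = c(FALSE, TRUE))
  if (sum(grp == TRUE) < 2) stop("target needs >= 2 replicates")
  if (sum(grp == FALSE) < 2) stop("rest needs >= 2 samples")
  sf <- sf %||% size_factors(counts)
  off <- log(sf)
  keep <- rowSums(counts) > 0
  excluded <- rownames(counts)[!keep]
  cts <- counts[keep, , drop = FALSE]
  theta_cap <- 1 / dispersion_floor
  res <- matrix(NA_real_, nrow(cts), 4,
                dimnames = list(rownames(cts),
                                c("log2_fold_change", "wald_statistic",
                                  "p_value", "dispersion")))
  for (g in seq_len(nrow(cts))) {
    y <- cts[g, ]
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ grp + offset(off))),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$theta) || fit$theta > theta_cap) {
      fit <- tryCatch(suppressWarnings(
        glm(y ~ grp + offset(off),
            family = MASS::negative.binomial(theta = theta_cap))),
        error = function(e) NULL)
      theta <- theta_cap
    } else theta <- fit$theta
    if (is.null(fit)) next
    sm <- summary(fit)$coefficients
    if (!"grpTRUE" %in% rownames(sm)) next
    b <- sm["grpTRUE", "Estimate"]; se <- sm["grpTRUE", "Std. Error"]
    res[g, ] <- c(b / log(2), b / se, 2 * pnorm(-abs(b / se)), 1 / theta)
  }
  out <- data.frame(gene = rownames(cts),
                    base_mean = rowMeans(sweep(cts, 2, sf, "/")),
                    log2_fold_change = res[, 1],
                    wald_statistic = res[, 2],
                    p_value = res[, 3],
                    p_adjusted = p.adjust(res[, 3], method = "BH"),
                    dispersion = res[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, contrast = paste0(target_phenotype, "_vs_rest"),
            size_factors = sf, excluded_genes = excluded,
            class = c("de_result", "data.frame"))
}

#' Derive disjoint phenotype gene signatures from one-vs-rest DE results
#'
#' Thresholds each phenotype's DE table (BH-adjusted p below `padj_max`
#' and signed log2 fold change above `log2fc_min`, i.e. up-regulation
#' only), then removes genes appearing in more than one provisional
#' signature so each final signature is phenotype-specific.
#'
#' @param de_results named list of [phenotype_de()] results (>= 2
#'   phenotypes, same gene universe).
#' @param padj_max,log2fc_min selection thresholds.
#' @return a `signature_set`: named list of gene vectors with attributes
#'   `removed_shared` (genes dropped by the uniqueness filter) and
#'   `thresholds`.
#' @export
derive_signatures <- function(de_results, padj_max = 0.05, log2fc_min = 2) {
  if (length(de_results) < 2) stop("need DE results for >= 2 phenotypes")
  if (is.null(names(de_results))) stop("de_results must be named")
  prov <- lapply(de_results, function(d) {
    sel <- !is.na(d$p_adjusted) & d$p_adjusted < padj_max &
      !is.na(d$log2_fold_change) & d$log2_fold_change > log2fc_min
    d$gene[sel]
  })
  all_genes <- unlist(prov, use.names = FALSE)
  shared <- unique(all_genes[duplicated(all_genes)])
  sigs <- lapply(prov, function(g) setdiff(g, shared))
  empty <- names(sigs)[vapply(sigs, length, integer(1)) == 0]
  if (length(empty))
    warning("empty signature(s) after filtering: ",
            paste(empty, collapse = ", "))
  structure(sigs, removed_shared = shared,
            thresholds = c(padj_max = padj_max, log2fc_min = log2fc_min),
            class = "signature_set")
}

#' Rank-based recovery-curve AUC signature score
#'
#' For each sample, genes are ranked by decreasing expression (ties broken
#' by gene order, deterministically) and the score is the area under the
#' recovery curve of signature genes within the top
#' `ceiling(top_fraction * G)` ranks, normalized by the maximum attainable
#' area, giving a value in `[0, 1]`: 1 when all signature genes head the
#' ranking, 0 when none enter the top fraction. The score depends on ranks
#' only, so it is invariant to monotone transforms of a sample's
#' expression.
#'
#' @param expression genes x samples numeric matrix (row names are gene
#'   ids).
#' @param signature character vector of gene ids; must intersect the rows.
#' @param top_fraction fraction of the ranking examined (in (0, 1)).
#' @return named numeric vector of per-sample scores in `[0, 1]`.
#' @export
score_auc <- function(expression, signature, top_fraction = 0.05) {
  expression <- as.matrix(expression)
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must lie in (0, 1)")
  if (!length(signature)) stop("signature is empty")
  sig <- intersect(signature, rownames(expression))
  if (!length(sig))
    stop("signature has no genes in the expression universe")
  G <- nrow(expression)
  Tn <- ceiling(top_fraction * G)
  maxarea <- sum(pmin(seq_len(Tn), length(sig)))
  in_sig <- rownames(expression) %in% sig
  apply(expression, 2, function(v) {
    ord <- order(-v, seq_along(v))
    hits <- cumsum(in_sig[ord][seq_len(Tn)])
    sum(hits) / maxarea
  })
}

#' Score every signature of a set across samples
#'
#' @param expression genes x samples matrix.
#' @param signatures a [derive_signatures()] result (or named list of gene
#'   vectors).
#' @param top_fraction see [score_auc()].
#' @return samples x signatures matrix of scores; signatures with no gene
#'   in the universe give NA columns (with a warning).
#' @export
score_signature_set <- function(expression, signatures,
                                top_fraction = 0.05) {
  out <- sapply(names(signatures), function(ph) {
    g <- signatures[[ph]]
    if (!length(intersect(g, rownames(expression)))) {
      warning("signature ", ph, " has no genes in the universe")
      return(rep(NA_real_, ncol(expression)))
    }
    score_auc(expression, g, top_fraction)
  })
  rownames(out) <- colnames(expression)
  out
}

#' Write and read gene sets in GMT format
#'
#' @param signatures named list of gene vectors.
#' @param path file path.
#' @param description optional per-set description column.
#' @return `write_gmt` returns `path` invisibly; `read_gmt` returns a
#'   named list of gene vectors.
#' @export
write_gmt <- function(signatures, path, description = NA) {
  lines <- vapply(names(signatures), function(nm) {
    paste(c(nm, if (is.na(description)) nm else description,
            signatures[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}
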