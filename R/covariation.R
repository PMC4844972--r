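#' Encode an alignment column on a property scale
#'
#' @param concat A [concatenate_alignments()] object.
#' @param col Column index.
#' @param scale A [property_scale()] (or its name).
#' @return Numeric vector (one value per species); gaps and `X` are `NA`.
#' @export
encode_column <- function(concat, col, scale = "volume") {
  stopifnot(inherits(concat, "kai_concat"))
  if (col < 1L || col > concat$n_col) stop("column index out of range: ", col)
  if (is.character(scale)) scale <- property_scale(scale)
  chars <- substr(concat$seqs, col, col)
  unname(scale[match(chars, AA_ALPHABET)])
}

#' Columns eligible for the co-variation scan
#'
#' Applies the two column filters of the scan: at most `gap_threshold` missing
#' residues (95% sequence coverage at the 0.05 default) and at least
#' `variability_threshold` distinct residue types (2 by default, excluding
#' invariant columns).
#'
#' @param concat A [concatenate_alignments()] object.
#' @param gap_threshold Maximum gap fraction (default 0.05).
#' @param variability_threshold Minimum number of distinct residues (default 2).
#' @return Integer vector of eligible column indices.
#' @export
eligible_columns <- function(concat, gap_threshold = 0.05,
                             variability_threshold = 2) {
  stopifnot(gap_threshold >= 0, gap_threshold <= 1, variability_threshold >= 1)
  rep_ <- alignment_report(concat)
  rep_$col[rep_$gap_fraction <= gap_threshold &
           rep_$n_distinct >= variability_threshold]
}

#' Pearson correlation of two property-encoded columns
#'
#' Pairwise-complete Pearson correlation with the Student-t test:
#' `t = r sqrt((n-2)/(1-r^2))`, two-sided p from t with `n-2` degrees of
#' freedom. With fewer than 3 complete pairs, or a zero-variance input, the
#' correlation is undefined and the record is flagged not significant.
#'
#' @param x,y Numeric vectors of equal length (may contain `NA`).
#' @param alpha Significance level (default 0.05).
#' @return One-row data frame: `n`, `r`, `t_stat`, `p_value`, `significant`.
#' @export
pair_correlation <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), alpha > 0, alpha < 1)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(data.frame(n = n, r = NA_real_, t_stat = NA_real_,
                      p_value = NA_real_, significant = FALSE))
  r <- cor(x[ok], y[ok])
  if (abs(r) >= 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  data.frame(n = n, r = r, t_stat = t_stat, p_value = p,
             significant = p < alpha)
}

#' Scan column pairs for physicochemical co-variation
#'
#' Computes [pair_correlation()] for all unordered pairs of eligible columns,
#' on each property scale, optionally restricted to inter-protein pairs or to
#' a user-supplied column set (e.g. candidate interface residues). No
#' multiple-testing correction is applied by default, matching a per-pair
#' significance level; set `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param concat A [concatenate_alignments()] object.
#' @param scales Character vector of scale names, or list of scales.
#' @param alpha Per-pair significance level (default 0.05).
#' @param gap_threshold,variability_threshold Column filters, see
#'   [eligible_columns()].
#' @param columns Optional integer vector restricting the scan to these
#'   columns (intersected with the eligible set).
#' @param inter_protein_only If `TRUE`, keep only pairs from different
#'   protein blocks.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame of class `kai_cor_records`, sorted by p-value: columns
#'   `col_i`, `col_j`, `label_i`, `label_j`, `scale`, `n`, `r`, `t_stat`,
#'   `p_value`, `significant`.
#' @export
scan_pairs <- function(concat, scales = c("volume", "polarity", "hydrophobicity"),
                       alpha = 0.05, gap_threshold = 0.05,
                       variability_threshold = 2, columns = NULL,
                       inter_protein_only = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  elig <- eligible_columns(concat, gap_threshold, variability_threshold)
  if (!is.null(columns)) elig <- intersect(elig, columns)
  if (length(elig) < 2L) {
    warning("fewer than 2 eligible columns; empty scan")
    return(structure(data.frame(), class = c("kai_cor_records", "data.frame")))
  }
  prot <- column_protein(concat)
  pairs <- t(combn(elig, 2L))
  if (inter_protein_only)
    pairs <- pairs[prot[pairs[, 1L]] != prot[pairs[, 2L]], , drop = FALSE]
  if (nrow(pairs) == 0L) {
    warning("no column pairs left after filtering; empty scan")
    return(structure(data.frame(), class = c("kai_cor_records", "data.frame")))
  }
  if (!is.list(scales)) scales <- as.list(scales)
  out <- vector("list", length(scales))
  for (s in seq_along(scales)) {
    sc <- scales[[s]]
    if (is.character(sc)) sc <- property_scale(sc)
    sname <- attr(sc, "scale_name")
    enc <- vapply(elig, function(j) encode_column(concat, j, sc),
                  numeric(length(concat$ids)))
    colnames(enc) <- as.character(elig)
    # vectorized pairwise-complete Pearson + t test over all pairs at once;
    # agrees with pair_correlation() (tested) but avoids a per-pair loop
    rmat <- suppressWarnings(cor(enc, use = "pairwise.complete.obs"))
    nmat <- crossprod(!is.na(enc))
    ii <- match(as.character(pairs[, 1L]), colnames(enc))
    jj <- match(as.character(pairs[, 2L]), colnames(enc))
    rv <- rmat[cbind(ii, jj)]
    nv <- nmat[cbind(ii, jj)]
    rv[nv < 3L] <- NA_real_
    tv <- ifelse(abs(rv) >= 1, sign(rv) * Inf,
                 rv * sqrt((nv - 2) / (1 - rv^2)))
    pv <- ifelse(is.infinite(tv), 0, 2 * pt(-abs(tv), df = pmax(nv - 2, 1)))
    recs <- data.frame(n = as.integer(nv), r = rv, t_stat = tv, p_value = pv,
                       significant = !is.na(pv) & pv < alpha)
    out[[s]] <- cbind(data.frame(col_i = pairs[, 1L], col_j = pairs[, 2L],
                                 label_i = column_label(concat, pairs[, 1L]),
                                 label_j = column_label(concat, pairs[, 2L]),
                                 scale = sname), recs)
  }
  out <- do.call(rbind, out)
  if (adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- !is.na(out$p_value) & out$p_value < alpha
  }
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  structure(out, class = c("kai_cor_records", "data.frame"))
}
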