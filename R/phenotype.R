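#' Aggregate an animal's faecal-score series
#'
#' Faeces are scored 0 (normal), 1 (soft, without diarrhoea) or 2 (evident
#' diarrhoea) on a panel of observation days. Three aggregates are derived:
#' \describe{
#'   \item{FS_sum}{number of diarrhoea records divided by the number of
#'     observations (a prevalence in `[0, 1]`).}
#'   \item{FS_gr}{group level: 0 = no diarrhoea record, 1 = exactly one,
#'     2 = two or more.}
#'   \item{FS_p_a}{presence/absence indicator of any diarrhoea record.}
#' }
#' By default only score 2 counts as a diarrhoea record (score 1 is
#' explicitly "without diarrhoea"); set `diarrhoea_level = 1` to also count
#' soft faeces.
#'
#' @param scores integer scores in `{0, 1, 2}`.
#' @param diarrhoea_level minimum score counted as a diarrhoea record
#'   (default 2).
#' @return A list with `FS_sum`, `FS_gr`, `FS_p_a` and `n_obs`.
#' @export
#' @examples
#' aggregate_faecal_scores(c(2, 2, 1, 0, 0, 0, 0, 0, 0))
aggregate_faecal_scores <- function(scores, diarrhoea_level = 2) {
  if (length(scores) < 1L) stop("need at least one observation", call. = FALSE)
  bad <- which(!scores %in% c(0, 1, 2))
  if (length(bad)) {
    stop(sprintf("invalid faecal score at observation %d: %s",
                 bad[1L], scores[bad[1L]]), call. = FALSE)
  }
  n <- length(scores)
  n_dia <- sum(scores >= diarrhoea_level)
  list(FS_sum = n_dia / n,
       FS_gr = if (n_dia == 0L) 0L else if (n_dia == 1L) 1L else 2L,
       FS_p_a = as.integer(n_dia > 0L),
       n_obs = n)
}

#' Neutrophil/lymphocyte ratio
#'
#' The N/Lym ratio of the neutrophil and lymphocyte percentages of the
#' leucocyte differential, used as a blood stress indicator.
#'
#' @param N neutrophils, %.
#' @param Lym lymphocytes, %.
#' @return `N / Lym`; `NA` (undefined) when `Lym` is 0 or missing.
#' @export
derive_n_lym <- function(N, Lym) {
  out <- N / Lym
  out[!is.na(Lym) & Lym == 0] <- NA_real_
  out
}

#' Log-normalise a trait vector
#'
#' @param values numeric trait values; must be strictly positive for a log
#'   base.
#' @param base `"none"` (identity), `2` or `10`.
#' @return The transformed vector, with attribute `transform` recording the
#'   choice.
#' @export
#' @examples
#' normalize_trait(c(1, 2, 4, 8), base = 2)
normalize_trait <- function(values, base = "none") {
  if (identical(base, "none")) {
    return(structure(values, transform = "none"))
  }
  if (!base %in% c(2, 10)) {
    stop('`base` must be "none", 2 or 10', call. = FALSE)
  }
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    stop("non-positive values cannot be log-transformed (positions ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  structure(log(values, base = base), transform = paste0("log", base))
}

#' Pearson or Spearman correlation with a t-approximation p-value
#'
#' Pearson's product-moment correlation, or Spearman's correlation computed
#' as Pearson on mid-ranks (average ranks for ties). The two-sided p-value
#' uses the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom for both methods. Incomplete pairs are dropped
#' (pairwise deletion).
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `p`, `n` (complete pairs) and `method`. With
#'   fewer than 4 complete pairs or zero variance, `r` and `p` are `NA`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L || stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, method = method))
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n, method = method)
}

#' Correlation screen of model parameters against phenotype traits
#'
#' Computes every parameter x trait correlation between two animal-keyed
#' tables and flags pairs significant at `alpha` (raw p-values, matching the
#' usual uncorrected P < 0.05 screen). Non-significant pairs are retained in
#' the output and simply flagged. A Benjamini-Hochberg adjusted p-value
#' (`p_adj`, per method) is emitted alongside as a labelled extension; it
#' plays no part in the `significant` flag.
#'
#' @param params_table data frame with an `animal_id` column and numeric
#'   model-parameter columns (e.g. mu0, D, C, ts, ABC, J).
#' @param phenotype_table data frame with an `animal_id` column and numeric
#'   trait columns.
#' @param alpha significance level for the raw-p screen (default 0.05).
#' @param methods correlation methods to run.
#' @return A long data frame: `parameter`, `trait`, `method`, `r`, `p`, `n`,
#'   `significant`, `p_adj`, sorted by method, parameter, trait.
#' @export
correlation_report <- function(params_table, phenotype_table, alpha = 0.05,
                               methods = c("pearson", "spearman")) {
  stopifnot(is.data.frame(params_table), is.data.frame(phenotype_table),
            "animal_id" %in% names(params_table),
            "animal_id" %in% names(phenotype_table))
  merged <- merge(params_table, phenotype_table, by = "animal_id",
                  suffixes = c("_param", "_trait"))
  if (nrow(merged) == 0L) {
    stop("no shared animal_id between the two tables", call. = FALSE)
  }
  is_num <- function(df) names(df)[vapply(df, is.numeric, logical(1))]
  pcols <- setdiff(is_num(params_table), "animal_id")
  tcols <- setdiff(is_num(phenotype_table), "animal_id")
  # merge() suffixes only clashing names
  pkey <- ifelse(pcols %in% tcols, paste0(pcols, "_param"), pcols)
  tkey <- ifelse(tcols %in% pcols, paste0(tcols, "_trait"), tcols)

  grid <- expand.grid(pi = seq_along(pcols), ti = seq_along(tcols),
                      method = methods, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    pi <- grid$pi[k]; ti <- grid$ti[k]
    res <- correlate(merged[[pkey[pi]]], merged[[tkey[ti]]],
                     method = grid$method[k])
    data.frame(parameter = pcols[pi], trait = tcols[ti],
               method = res$method, r = res$r, p = res$p, n = res$n)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha
  out$p_adj <- NA_real_
  for (m in unique(out$method)) {
    sel <- out$method == m
    out$p_adj[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out <- out[order(out$method, out$parameter, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  out
}
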