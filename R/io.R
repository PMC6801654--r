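#' Load body-weight trajectories from CSV
#'
#' Expects a comma-separated file with header `animal_id,time_days,weight_kg`
#' ('.' decimal separator, UTF-8), times in days since weaning. Rows with
#' non-positive weight, negative time or missing values are rejected with a
#' message naming their line numbers; remaining rows are grouped by animal
#' and sorted by time. Animals lacking a t = 0 record are kept but flagged in
#' the `missing_t0` attribute (they cannot be calibrated, since the weaning
#' weight anchors `W0`).
#'
#' @param path CSV file path.
#' @return A named list of [weight_trajectory()] objects, with attributes
#'   `rejected_lines` (integer line numbers, header = line 1) and
#'   `missing_t0` (animal ids).
#' @export
load_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "time_days", "weight_kg")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty weights file: ", path, call. = FALSE)
  bad <- which(is.na(df$time_days) | is.na(df$weight_kg) |
                 df$weight_kg <= 0 | df$time_days < 0)
  if (length(bad)) {
    message("load_weights: rejected ", length(bad), " row(s) at line(s) ",
            paste(bad + 1L, collapse = ", "),
            " (non-positive weight, negative time or missing value)")
    df <- df[-bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid rows in ", path, call. = FALSE)

  out <- list(); missing_t0 <- character()
  for (id in sort(unique(df$animal_id))) {
    sub <- df[df$animal_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_days), , drop = FALSE]
    sub <- sub[!duplicated(sub$time_days), , drop = FALSE]
    if (sub$time_days[1L] != 0 || nrow(sub) < 2L) {
      missing_t0 <- c(missing_t0, as.character(id))
      next
    }
    out[[as.character(id)]] <-
      weight_trajectory(id, sub$time_days, sub$weight_kg)
  }
  if (length(missing_t0)) {
    message("load_weights: ", length(missing_t0),
            " animal(s) lack a t = 0 weighing (or have < 2 records): ",
            paste(missing_t0, collapse = ", "))
  }
  structure(out, rejected_lines = if (length(bad)) bad + 1L else integer(),
            missing_t0 = missing_t0)
}

#' Load faecal scores from CSV
#'
#' Expects header `animal_id,day,score` with scores in `{0, 1, 2}` and days
#' since weaning. Invalid rows are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return A data frame `animal_id`, `day`, `score` sorted by animal and day.
#' @export
load_faecal_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "day", "score")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(df$day) | df$day < 0 | !df$score %in% c(0, 1, 2))
  if (length(bad)) {
    message("load_faecal_scores: rejected ", length(bad),
            " row(s) at line(s) ", paste(bad + 1L, collapse = ", "))
    df <- df[-bad, , drop = FALSE]
  }
  df <- df[order(df$animal_id, df$day), , drop = FALSE]
  df <- df[!duplicated(df[, c("animal_id", "day")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Load haemograms from CSV
#'
#' Expects header `animal_id,age_days` plus the 13 trait columns (`Bas`,
#' `Plt`, `Eos`, `Ery`, `Hct`, `Hgb`, `Leu`, `Lym`, `MCHC`, `MCH`, `MCV`,
#' `Mon`, `N`). The derived `N_Lym` stress ratio is appended.
#'
#' @param path CSV file path.
#' @return The haemogram data frame with an `N_Lym` column added.
#' @export
load_haemograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "age_days", default_haem_loadings()$trait)
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$N_Lym <- derive_n_lym(df$N, df$Lym)
  df
}

# CSV writer preserving doubles exactly: 17 significant digits round-trip
# through read.csv without loss
write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the three tables the pipeline consumes (`weights.csv`, `faecal.csv`,
#' `haemogram.csv`) plus the generating `truth.csv` for parameter-recovery
#' scoring.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("weights.csv", "faecal.csv", "haemogram.csv",
                            "truth.csv"))
  write_csv_full(cohort$weights, paths[1L])
  write_csv_full(cohort$faecal, paths[2L])
  write_csv_full(cohort$haemogram, paths[3L])
  write_csv_full(cohort$truth, paths[4L])
  invisible(paths)
}
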