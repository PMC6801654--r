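#' Fit both growth models and the reference curve across a cohort
#'
#' Runs, per animal: the classic Gompertz fit, the perturbed
#' (Gompertz-Makeham) fit, the unperturbed reference fit, AIC comparison and
#' the ABC resilience index. Animals with too few usable records are flagged
#' and skipped, never dropped silently.
#'
#' @param trajectories a list of [weight_trajectory()] objects.
#' @param cfg a [calibration_config()].
#' @return A list with
#'   \describe{
#'     \item{fits}{long per-animal/per-model fit table (`animal_id`, `model`,
#'       `mu0`, `D`, `C`, `ts`, `J`, `J_raw`, `r2`, `ccc`, `aic`, `n_t`,
#'       `converged`).}
#'     \item{ranking}{[rank_by_J()] table from the Gompertz fits.}
#'     \item{resilience}{per-animal table `animal_id`, `mu0`, `D`, `C`, `ts`,
#'       `J`, `ABC`, `intersection_time`, `censored`, `abc_flagged`,
#'       `J_rank`, `preferred_model`.}
#'     \item{fit_objects}{the raw `fit_result`s, per animal and model.}
#'     \item{skipped}{data frame of skipped animals and reasons.}
#'   }
#' @export
fit_cohort <- function(trajectories, cfg = calibration_config()) {
  stopifnot(length(trajectories) >= 1L)
  fits <- list(); skipped <- list(); objects <- list()

  for (tr in trajectories) {
    id <- tr$animal_id
    res <- tryCatch({
      g <- fit_gompertz(tr, cfg)
      p <- fit_perturbed(tr, cfg)
      u <- fit_unperturbed_reference(tr, cfg)
      list(g = g, p = p, u = u)
    }, weanres_skip = function(e) e)
    if (inherits(res, "weanres_skip")) {
      skipped[[id]] <- data.frame(animal_id = id,
                                  reason = conditionMessage(res))
      next
    }
    objects[[id]] <- res
    fits[[id]] <- do.call(rbind, lapply(
      list(res$g, res$p, res$u), function(f) {
        pp <- f$params
        data.frame(animal_id = f$animal_id, model = f$model_name,
                   mu0 = pp$mu0, D = pp$D,
                   C = if (inherits(pp, "perturbed_params")) pp$C else NA_real_,
                   ts = if (inherits(pp, "perturbed_params")) pp$ts else NA_real_,
                   J = f$J, J_raw = f$J_raw, r2 = f$r2, ccc = f$ccc,
                   aic = f$aic, n_t = f$n_t, converged = f$converged)
      }))
  }
  if (length(objects) == 0L) {
    stop("no animal could be calibrated", call. = FALSE)
  }
  fit_table <- do.call(rbind, fits)
  rownames(fit_table) <- NULL

  ranking <- rank_by_J(lapply(objects, function(o) o$g))

  resilience <- do.call(rbind, lapply(objects, function(o) {
    abc <- compute_abc(o$u$params, o$p$params, cfg$horizon_days)
    pp <- o$p$params
    data.frame(animal_id = o$p$animal_id,
               mu0 = pp$mu0, D = pp$D, C = pp$C, ts = pp$ts, J = o$p$J,
               ABC = as.numeric(abc),
               intersection_time = attr(abc, "intersection_time"),
               censored = attr(abc, "censored"),
               abc_flagged = as.numeric(abc) < 0 || attr(abc, "pre_ts_crossing"),
               preferred_model = if (o$p$aic < o$g$aic) "perturbed" else "gompertz")
  }))
  resilience <- merge(resilience, ranking[, c("animal_id", "J_rank")],
                      by = "animal_id", sort = TRUE)
  rownames(resilience) <- NULL

  list(fits = fit_table, ranking = ranking, resilience = resilience,
       fit_objects = objects,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(animal_id = character(), reason = character()))
}

# per-animal faecal aggregates + wide haemogram (traits suffixed by age)
build_phenotype_table <- function(faecal = NULL, haemogram = NULL) {
  pieces <- list()
  if (!is.null(faecal) && nrow(faecal)) {
    pieces$fs <- do.call(rbind, lapply(split(faecal, faecal$animal_id),
      function(sub) {
        agg <- aggregate_faecal_scores(sub$score)
        data.frame(animal_id = sub$animal_id[1L], FS_sum = agg$FS_sum,
                   FS_gr = agg$FS_gr, FS_p_a = agg$FS_p_a)
      }))
  }
  if (!is.null(haemogram) && nrow(haemogram)) {
    h <- haemogram
    if (!"N_Lym" %in% names(h)) h$N_Lym <- derive_n_lym(h$N, h$Lym)
    traits <- setdiff(names(h), c("animal_id", "age_days"))
    for (age in sort(unique(h$age_days))) {
      sub <- h[h$age_days == age, c("animal_id", traits), drop = FALSE]
      names(sub)[-1L] <- paste0(traits, "_", age)
      pieces[[paste0("h", age)]] <- sub
    }
  }
  if (length(pieces) == 0L) return(NULL)
  out <- Reduce(function(a, b) merge(a, b, by = "animal_id", all = TRUE),
                pieces)
  rownames(out) <- NULL
  out
}

#' Run the full resilience pipeline
#'
#' End-to-end orchestration: per-animal Gompertz fit and J-ranking, perturbed
#' fit and AIC comparison, unperturbed reference fit, ABC index, phenotype
#' aggregation and the parameter-trait correlation screen. All result tables
#' are written as CSV to `output_dir` together with a JSON run manifest
#' (configuration echo, seed, package version, animal counts and skip
#' reasons) that suffices to reproduce the run; outputs are deterministic for
#' a fixed configuration.
#'
#' @param input either a [generate_cohort()] result, or a named list of file
#'   paths with `weights` (required), `faecal`, `haemogram` (optional).
#' @param output_dir directory for the result tables (created if needed);
#'   `NULL` to skip writing.
#' @param calibration a [calibration_config()].
#' @param alpha significance level of the correlation screen.
#' @return Invisibly, a list with `fits`, `ranking`, `resilience`,
#'   `population_summary`, `phenotypes`, `correlations`, `skipped`,
#'   `manifest`.
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_animals = 6, seed = 42))
#' res <- run_pipeline(coh, output_dir = NULL)
#' res$population_summary
#' }
run_pipeline <- function(input, output_dir = NULL,
                         calibration = calibration_config(),
                         alpha = 0.05) {
  if (inherits(input, "synthetic_cohort")) {
    trajectories <- input$trajectories
    faecal <- input$faecal
    haemogram <- input$haemogram
    source_desc <- list(type = "synthetic",
                        seed = input$config$seed,
                        n_animals = input$config$n_animals,
                        noise_cv = input$config$noise_cv)
  } else if (is.list(input) && !is.null(input$weights)) {
    trajectories <- load_weights(input$weights)
    faecal <- if (!is.null(input$faecal)) load_faecal_scores(input$faecal)
    haemogram <- if (!is.null(input$haemogram)) load_haemograms(input$haemogram)
    source_desc <- list(type = "files", paths = input)
  } else {
    stop("`input` must be a synthetic_cohort or a list with a `weights` path",
         call. = FALSE)
  }

  cohort <- fit_cohort(trajectories, calibration)

  summary_tab <- summarize_population(
    cohort$resilience, columns = c("mu0", "D", "C", "ts", "J", "ABC"))

  phenotypes <- build_phenotype_table(faecal, haemogram)
  correlations <- NULL
  if (!is.null(phenotypes)) {
    params_table <- cohort$resilience[
      , c("animal_id", "mu0", "D", "C", "ts", "J", "ABC")]
    correlations <- correlation_report(params_table, phenotypes, alpha)
  }

  manifest <- list(
    package = "weanres",
    version = as.character(utils::packageVersion("weanres")),
    source = source_desc,
    calibration = unclass(calibration),
    alpha = alpha,
    n_animals_in = length(trajectories),
    n_animals_fit = length(cohort$fit_objects),
    n_animals_skipped = nrow(cohort$skipped),
    skipped = cohort$skipped,
    aic_preferred_perturbed =
      sum(cohort$resilience$preferred_model == "perturbed")
  )

  out <- list(fits = cohort$fits, ranking = cohort$ranking,
              resilience = cohort$resilience,
              population_summary = summary_tab,
              phenotypes = phenotypes, correlations = correlations,
              skipped = cohort$skipped, manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      if (!is.null(df)) write_csv_full(df, file.path(output_dir, name))
    }
    wr(out$fits, "fits.csv")
    wr(out$ranking, "j_ranking.csv")
    wr(out$resilience, "resilience.csv")
    wr(out$population_summary, "population_summary.csv")
    wr(out$phenotypes, "phenotypes.csv")
    wr(out$correlations, "correlations.csv")
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
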