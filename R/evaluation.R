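#' Percent modulation of a unit by a stimulus variant
#'
#' The unit-level sensitivity statistic:
#' `(r_base - r_variant) / r_base * 100`.  Positive values mean the variant
#' drives the unit less than the base; negative values (variant excites
#' more) are allowed.  Comparisons whose base response does not exceed
#' `eps` are excluded (returned as `NA`).
#'
#' @param r_base response(s) to the base stimulus.
#' @param r_variant response(s) to the variant.
#' @param eps smallest admissible base response.
#' @return percent modulation (vectorized); `NA` where `r_base <= eps`.
#' @examples
#' percent_modulation(2, 1)    # 50
#' percent_modulation(0.5, 0.6)  # -20
#' @export
percent_modulation <- function(r_base, r_variant, eps = 1e-6) {
  out <- (r_base - r_variant) / r_base * 100
  out[r_base <= eps] <- NA_real_
  out
}

#' Responsiveness criterion for unit selection
#'
#' Controls which (unit, family) pairs enter the modulation analysis.
#' The default rule, `"preferred"`, keeps exactly one comparison per unit:
#' the family whose base image drives the unit most strongly (its
#' preferred stimulus), provided that response exceeds the absolute
#' `floor`.  Probing each unit at its preferred stimulus is what makes
#' percent modulation interpretable — away from the preferred stimulus a
#' "variant" can easily excite the unit *more* than the base, and the
#' statistic degenerates into noise around zero.
#'
#' The alternative rule, `"percentile"`, keeps every pair whose base
#' response exceeds the larger of the `floor` and the unit's own
#' `quantile`-th percentile of base responses across families (scale-free,
#' several comparisons per unit).  A bare number may be supplied to
#' [select_comparisons()] instead of a criterion object for a fixed
#' absolute threshold on all pairs.
#'
#' The default floor depends on the rule.  For `"preferred"` it is 0.5 —
#' half-maximal response on the C2 scale where a blank input scores ~0.02
#' and a perfect match 1 — so a unit only counts as visually responsive
#' when its preferred base image genuinely contains its feature.  Below
#' that regime the percent-modulation statistic degenerates: variants of a
#' stimulus that barely drives the unit routinely excite it more than the
#' base does.  For `"percentile"` the default floor is the permissive
#' 0.05.
#'
#' @param rule `"preferred"` or `"percentile"`.
#' @param quantile per-unit percentile in \[0, 1) (percentile rule only).
#' @param floor absolute threshold on the base response (default by rule,
#'   see above).
#' @return an object of class `responsiveness_criterion`.
#' @export
responsiveness_criterion <- function(rule = c("preferred", "percentile"),
                                     quantile = 0.5, floor = NULL) {
  rule <- match.arg(rule)
  if (is.null(floor)) floor <- if (rule == "preferred") 0.5 else 0.05
  stopifnot(quantile >= 0, quantile < 1, floor >= 0)
  structure(list(rule = rule, quantile = quantile, floor = floor),
            class = "responsiveness_criterion")
}

#' C2 responses of both model variants to a stimulus set
#'
#' Encodes every image of every family with the extended feature columns
#' and, from the same C2 pass, with their matched single-view baseline
#' (the first view of each column) — the original model.
#'
#' @param stim_set a [build_stimulus_set()] result.
#' @param columns a [learn_columns()] result.
#' @param model an [hmax_model()].
#' @return a tibble with columns `model` ("original"/"extended"),
#'   `unit_id`, `family_id`, `stimulus` ("base", "mp1".."mp4", "nap") and
#'   `response`.
#' @export
stimulus_responses <- function(stim_set, columns, model = hmax_model()) {
  stopifnot(inherits(stim_set, "stim_set"))
  stim_names <- c("base", paste0("mp", 1:4), "nap")
  rows <- list()
  for (f in stim_set$families) {
    imgs <- c(list(f$base), f$mp, list(f$nap))
    for (k in seq_along(imgs)) {
      both <- encode_both(imgs[[k]], columns, model)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = rep(c("original", "extended"),
                    each = length(both$original)),
        unit_id = rep(names(both$original), 2L),
        family_id = f$family_id,
        stimulus = stim_names[k],
        response = c(unname(both$original), unname(both$extended)))
    }
  }
  dplyr::bind_rows(rows)
}

#' Select responsive (unit, family) comparisons
#'
#' @param responses a [stimulus_responses()] tibble (one or both models).
#' @param criterion a [responsiveness_criterion()], or a single number used
#'   as an absolute threshold.
#' @return tibble of kept pairs: `model`, `unit_id`, `family_id`, `r_base`.
#' @export
select_comparisons <- function(responses,
                               criterion = responsiveness_criterion()) {
  base <- dplyr::filter(responses, .data$stimulus == "base")
  if (is.numeric(criterion) && length(criterion) == 1L) {
    kept <- dplyr::filter(base, .data$response > criterion)
  } else if (inherits(criterion, "responsiveness_criterion") &&
             criterion$rule == "preferred") {
    kept <- base |>
      dplyr::group_by(.data$model, .data$unit_id) |>
      dplyr::slice_max(.data$response, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$response > criterion$floor)
  } else if (inherits(criterion, "responsiveness_criterion")) {
    kept <- base |>
      dplyr::group_by(.data$model, .data$unit_id) |>
      dplyr::mutate(.thr = pmax(
        stats::quantile(.data$response, criterion$quantile, names = FALSE),
        criterion$floor)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$response > .data$.thr) |>
      dplyr::select(-".thr")
  } else {
    stop("`criterion` must be a responsiveness_criterion or a number",
         call. = FALSE)
  }
  if (nrow(kept) == 0L) {
    stop("no (unit, family) pair passes the responsiveness criterion; lower the threshold",
         call. = FALSE)
  }
  kept |>
    dplyr::select("model", "unit_id", "family_id", r_base = "response")
}

#' NAP-versus-MP modulation analysis
#'
#' For every selected (unit, family) pair, computes the percent modulation
#' of the unit from the base image to the NAP variant and to each MP
#' variant, then summarizes NAP against the headline MP level: mean
#' modulations, a paired two-sided Wilcoxon signed-rank test, and the
#' percentage of comparisons more strongly modulated by the NAP change.
#'
#' @param responses a [stimulus_responses()] tibble for a single model
#'   variant (filter first if it holds both).
#' @param criterion passed to [select_comparisons()].
#' @param headline_mp_level which MP step is compared against NAP
#'   (default 2, the level the NAP variant is pixel-calibrated against).
#' @param eps smallest admissible base response (see
#'   [percent_modulation()]).
#' @return an object of class `nap_modulation`: list with `records` (one
#'   row per comparison) and `summary` (one row).  If fewer than 5 nonzero
#'   paired differences exist the Wilcoxon p is reported as 1 with
#'   `degenerate = TRUE`.
#' @export
modulation_analysis <- function(responses,
                                criterion = responsiveness_criterion(),
                                headline_mp_level = 2L, eps = 1e-6) {
  if (dplyr::n_distinct(responses$model) != 1L) {
    stop("`responses` must contain a single model variant; filter first",
         call. = FALSE)
  }
  kept <- select_comparisons(responses, criterion)
  wide <- responses |>
    tidyr::pivot_wider(names_from = "stimulus", values_from = "response") |>
    dplyr::inner_join(kept, by = c("model", "unit_id", "family_id"))
  records <- wide |>
    dplyr::mutate(
      delta_nap = percent_modulation(.data$r_base, .data$nap, eps),
      delta_mp1 = percent_modulation(.data$r_base, .data$mp1, eps),
      delta_mp2 = percent_modulation(.data$r_base, .data$mp2, eps),
      delta_mp3 = percent_modulation(.data$r_base, .data$mp3, eps),
      delta_mp4 = percent_modulation(.data$r_base, .data$mp4, eps)) |>
    dplyr::select("model", "unit_id", "family_id", "r_base",
                  dplyr::starts_with("delta_"))
  n_excluded <- sum(is.na(records$delta_nap))
  if (n_excluded > 0L) {
    message(sprintf("%d comparison(s) excluded: base response below %g",
                    n_excluded, eps))
    records <- dplyr::filter(records, !is.na(.data$delta_nap))
  }
  mp_col <- paste0("delta_mp", headline_mp_level)
  dn <- records$delta_nap
  dm <- records[[mp_col]]
  degenerate <- sum(dn - dm != 0) < 5L
  p <- if (degenerate) 1 else wilcoxon_signed_rank(dn, dm)$p.value
  summary <- tibble::tibble(
    model = records$model[1],
    mean_nap_modulation = mean(dn),
    mean_mp_modulation = mean(dm),
    headline_mp_level = as.integer(headline_mp_level),
    n_comparisons = nrow(records),
    wilcoxon_p = p,
    frac_nap_gt_mp = 100 * mean(dn > dm),
    degenerate = degenerate)
  structure(list(records = records, summary = summary,
                 criterion = criterion,
                 headline_mp_level = as.integer(headline_mp_level)),
            class = "nap_modulation")
}

#' @export
print.nap_modulation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<nap_modulation> %s model: %.1f%% NAP vs %.1f%% MP%d modulation over n = %d comparisons\n  Wilcoxon p = %.3g; %.0f%% of units more modulated by NAP%s\n",
    s$model, s$mean_nap_modulation, s$mean_mp_modulation,
    s$headline_mp_level, s$n_comparisons, s$wilcoxon_p, s$frac_nap_gt_mp,
    if (s$degenerate) " [degenerate]" else ""))
  invisible(x)
}
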