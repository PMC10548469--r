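#' Convert kcal to kJ
#'
#' Exact linear conversion (1 kcal = 4.184 kJ); rounding happens only at
#' display time.
#'
#' @param value_kcal numeric, kcal (or kcal/atom).
#' @return value in kJ (or kJ/atom).
#' @export
convert_units <- function(value_kcal) {
  stopifnot(is.numeric(value_kcal))
  value_kcal * 4.184
}

#' Display rounding for reported energies
#'
#' Three decimals, round-half-even (IEEE banker's rounding as implemented
#' by base [round()]), matching the precision used in reports.
#'
#' @param x numeric.
#' @param digits decimals (default 3).
#' @export
display_round <- function(x, digits = 3) round(x, digits)

#' Summarize search results into interaction statistics
#'
#' Aggregates one binding energy per search - the minimum (most negative)
#' pose total, normalized per probe atom - into per-group means and sample
#' standard deviations (n-1 denominator), with component means and both
#' unit systems (kcal/atom and kJ/atom).
#'
#' @param results list of `search_result` objects (e.g. from
#'   [pair_matrix()]`$results`).
#' @param grouping character vector, one group label per result (e.g.
#'   `"API-API"` for cohesive pairs, `"API-carrier"` for adhesive ones).
#' @return data.frame of class `interaction_summary`: group, n, mean and sd
#'   (kcal/atom and kJ/atom), component means.
#' @export
summarize_interactions <- function(results, grouping) {
  stopifnot(length(results) == length(grouping))
  vals <- vapply(results, best_energy, numeric(1))
  disp <- vapply(results, function(r) r$poses$dispersive_per_atom[1], numeric(1))
  elec <- vapply(results, function(r) r$poses$electrostatic_per_atom[1], numeric(1))
  hb <- vapply(results, function(r) r$poses$hbond_per_atom[1], numeric(1))
  groups <- unique(grouping)
  rows <- lapply(groups, function(g) {
    ix <- which(grouping == g)
    if (length(ix) == 0) return(NULL)
    v <- vals[ix]
    data.frame(group = g, n = length(ix),
               mean_kcal_atom = mean(v),
               sd_kcal_atom = if (length(ix) > 1) stats::sd(v) else 0,
               mean_kj_atom = convert_units(mean(v)),
               sd_kj_atom = convert_units(if (length(ix) > 1) stats::sd(v) else 0),
               dispersive_kcal_atom = mean(disp[ix]),
               electrostatic_kcal_atom = mean(elec[ix]),
               hbond_kcal_atom = mean(hb[ix]),
               polar_kcal_atom = mean(elec[ix] + hb[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("interaction_summary", "data.frame")
  out
}

#' Gaussian fit of an energy histogram
#'
#' Least-squares fit of a Gaussian bell `A exp(-(x - mu)^2 / (2 sd^2))` to
#' binned pose energies, returning location, scale and fit diagnostics.
#' Degenerate histograms (< 3 nonempty bins) fall back to the
#' count-weighted sample mean and standard deviation, flagged in the
#' result.
#'
#' @param hist an [energy_histogram()] (or list with `mids`, `counts`).
#' @return list: `mean`, `sd`, `amplitude`, `rss` (residual sum of
#'   squares), `fallback` (TRUE if moments were used), `converged`.
#' @export
gaussian_fit <- function(hist) {
  mids <- hist$mids
  counts <- as.numeric(hist$counts)
  keep <- counts > 0
  mids <- mids[keep]; counts <- counts[keep]
  if (length(mids) == 0) stop("empty histogram", call. = FALSE)
  wmean <- sum(mids * counts) / sum(counts)
  wsd <- sqrt(sum(counts * (mids - wmean)^2) / max(sum(counts) - 1, 1))
  if (length(mids) < 3 || wsd == 0) {
    return(list(mean = wmean, sd = wsd, amplitude = max(counts),
                rss = 0, fallback = TRUE, converged = NA))
  }
  df <- data.frame(x = mids, y = counts)
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
    start = list(A = max(counts), mu = wmean, s = wsd),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(mean = wmean, sd = wsd, amplitude = max(counts),
                rss = NA_real_, fallback = TRUE, converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(mean = unname(cf["mu"]), sd = abs(unname(cf["s"])),
       amplitude = unname(cf["A"]),
       rss = sum(stats::residuals(fit)^2),
       fallback = FALSE, converged = TRUE)
}

#' Cohesive-adhesive balance classification
#'
#' Compares the mean cohesive (API-API) binding energy with the mean
#' adhesive (API-excipient) binding energy. If cohesion is more negative
#' by more than the margin threshold, the blend is cohesively balanced and
#' segregation of the API from the excipient is predicted. Otherwise the
#' blend is adhesively balanced (fines disperse over the carrier): a blend
#' whose adhesion matches or exceeds its cohesion mixes intimately, so
#' near-equal strengths fall on the adhesive side, and only an exact tie -
#' which carries no information either way - is reported indeterminate.
#' The verdict always carries the margin and the strength ordering of all
#' groups so the threshold can be revisited.
#'
#' @param summaries an `interaction_summary` (from
#'   [summarize_interactions()]).
#' @param api_label,excipient_label component labels as used in the group
#'   names (`"A-B"` convention, order-insensitive for adhesive pairs).
#' @param margin_threshold minimum mean-energy difference (kcal/atom) to
#'   call a winner (default 0.01).
#' @return Object of class `balance_verdict`: `classification`
#'   (`"cohesively-balanced"`, `"adhesively-balanced"` or
#'   `"indeterminate"`), `segregation_predicted`, `margin` (kcal/atom,
#'   positive when cohesion dominates), `ordering` (e.g.
#'   `"A-A > A-B > B-B"`, strongest first), and the two means.
#' @export
classify_balance <- function(summaries, api_label, excipient_label,
                             margin_threshold = 0.01) {
  stopifnot(inherits(summaries, "data.frame"))
  g <- summaries$group
  coh_name <- paste(api_label, api_label, sep = "-")
  adh_names <- c(paste(api_label, excipient_label, sep = "-"),
                 paste(excipient_label, api_label, sep = "-"))
  coh <- summaries$mean_kcal_atom[g == coh_name]
  adh <- summaries$mean_kcal_atom[g %in% adh_names]
  if (length(coh) == 0) stop("missing cohesive entry '", coh_name, "'",
                             call. = FALSE)
  if (length(adh) == 0) stop("missing adhesive entry '", adh_names[1], "'",
                             call. = FALSE)
  coh_mean <- mean(coh); adh_mean <- mean(adh)
  margin <- adh_mean - coh_mean   # > 0: cohesion more negative (stronger)
  classification <- if (margin > margin_threshold) "cohesively-balanced"
                    else if (abs(margin) <= .Machine$double.eps * 4 *
                             max(abs(coh_mean), abs(adh_mean), 1))
                      "indeterminate"
                    else "adhesively-balanced"
  ordering <- paste(g[order(summaries$mean_kcal_atom)], collapse = " > ")
  structure(list(classification = classification,
                 segregation_predicted = classification == "cohesively-balanced",
                 margin = margin,
                 cohesive_mean = coh_mean, adhesive_mean = adh_mean,
                 ordering = ordering,
                 margin_threshold = margin_threshold),
            class = "balance_verdict")
}

#' @export
print.balance_verdict <- function(x, ...) {
  cat(sprintf("blend balance: %s (margin %.4f kcal/atom, threshold %.4f)\n",
              x$classification, x$margin, x$margin_threshold))
  cat(sprintf("  cohesive mean %.4f, adhesive mean %.4f kcal/atom\n",
              x$cohesive_mean, x$adhesive_mean))
  cat(sprintf("  strength order: %s\n", x$ordering))
  if (x$segregation_predicted) cat("  blend segregation predicted\n")
  invisible(x)
}

#' Area-weighted mean of per-face values
#'
#' Weighted mean `sum(v_i a_i) / sum(a_i)` for combining per-face energies
#' into a whole-particle estimate using the faces' exposed areas.
#'
#' @param face_values numeric values per face.
#' @param face_areas areas (>= 0, same length, positive total).
#' @export
area_weighted_energy <- function(face_values, face_areas) {
  if (length(face_values) != length(face_areas)) {
    stop("values and areas must have equal length", call. = FALSE)
  }
  if (any(face_areas < 0) || sum(face_areas) <= 0) {
    stop("areas must be >= 0 with positive total", call. = FALSE)
  }
  sum(face_values * face_areas) / sum(face_areas)
}

#' Write an interaction summary and verdict to files
#'
#' @param summaries an `interaction_summary`.
#' @param verdict a `balance_verdict` (optional).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_blend_report <- function(summaries, verdict = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "interaction_summary.csv")
  utils::write.csv(as.data.frame(summaries), csv, row.names = FALSE)
  paths <- csv
  if (!is.null(verdict)) {
    js <- file.path(dir, "balance_verdict.json")
    jsonlite::write_json(unclass(verdict), js, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, js)
  }
  invisible(paths)
}
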