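# Enzyme kinetics post-processing: Michaelis-Menten fitting, relative
# activities and thermal-inactivation profiles.

#' Fit Michaelis-Menten kinetics to initial-rate data
#'
#' Nonlinear least-squares fit of `v = Vmax * S / (KM + S)` via
#' Levenberg-Marquardt (`minpack.lm::nlsLM`), started from the closed-form
#' Hanes-Woolf linearisation (`S/v` on `S`).  With replicate-labelled data
#' (>= 3 replicates) each replicate is fitted separately and parameters are
#' reported as mean +- SD across replicates, matching the usual
#' "average of n measurements +- SD" convention; otherwise SDs come from
#' the fit covariance.
#'
#' @param data data.frame with columns `substrate_uM` and `rate`, optionally
#'   `rep` (replicate id).  At least 4 distinct positive concentrations.
#' @param enzyme_conc enzyme concentration in the same molar unit as the
#'   substrate (uM); `k_cat = Vmax / enzyme_conc`, so `rate` must be in
#'   concentration of product per second for k_cat in 1/s.
#' @return An object of class `mm_fit`: list with `km`, `km_sd`, `vmax`,
#'   `vmax_sd`, `kcat`, `kcat_sd`, `efficiency` (`kcat / KM` in 1/(M s)),
#'   `n_replicates`, `flags`, `data`, and per-replicate parameter table
#'   `replicates` when applicable.
#' @export
fit_michaelis_menten <- function(data, enzyme_conc) {
  if (enzyme_conc <= 0) stop2("enzyme_conc must be positive")
  req <- c("substrate_uM", "rate")
  if (!all(req %in% names(data)))
    stop2("data needs columns substrate_uM and rate")
  if (any(data$substrate_uM <= 0)) stop2("substrate concentrations must be positive")
  if (length(unique(data$substrate_uM)) < 4)
    stop2("need >= 4 distinct substrate concentrations")

  reps <- if ("rep" %in% names(data)) unique(data$rep) else NULL
  if (!is.null(reps) && length(reps) >= 3) {
    per <- lapply(reps, function(r)
      fit_mm_single(data[data$rep == r, , drop = FALSE]))
    km <- vapply(per, `[[`, numeric(1), "km")
    vmax <- vapply(per, `[[`, numeric(1), "vmax")
    out <- list(km = mean(km), km_sd = sd(km),
                vmax = mean(vmax), vmax_sd = sd(vmax),
                n_replicates = length(reps),
                replicates = data.frame(rep = reps, km = km, vmax = vmax),
                sd_source = "replicates")
  } else {
    f <- fit_mm_single(data)
    out <- list(km = f$km, km_sd = f$km_sd, vmax = f$vmax,
                vmax_sd = f$vmax_sd, n_replicates = 1L,
                sd_source = "covariance")
  }
  out$kcat <- out$vmax / enzyme_conc
  out$kcat_sd <- out$vmax_sd / enzyme_conc
  out$enzyme_conc <- enzyme_conc
  out$efficiency <- out$kcat / (out$km * 1e-6)  # KM uM -> M
  out$flags <- character(0)
  if (out$km <= 0 || out$km > 10 * max(data$substrate_uM)) {
    out$flags <- "km_outside_range"
    warn2("fitted KM outside (0, 10 * max S): saturation poorly identified")
  }
  out$data <- data
  class(out) <- "mm_fit"
  out
}

# single-dataset Michaelis-Menten fit; Hanes-Woolf start values
fit_mm_single <- function(df) {
  S <- df$substrate_uM; v <- df$rate
  if (var(v) == 0) stop2("all rates identical: Michaelis-Menten fit unidentifiable")
  hw <- lm(I(S / v) ~ S)
  vmax0 <- 1 / coef(hw)[[2]]
  km0 <- coef(hw)[[1]] * vmax0
  if (!is.finite(km0) || km0 <= 0) km0 <- median(S)
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop2("Michaelis-Menten fit did not converge (start: Vmax = ",
            signif(vmax0, 4), ", Km = ", signif(km0, 4), "): ",
            conditionMessage(e)))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  list(km = cf[["Km"]], vmax = cf[["Vmax"]],
       km_sd = se[["Km"]], vmax_sd = se[["Vmax"]], fit = fit)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit",
      if (x$n_replicates > 1) sprintf("(%d replicates, SD across replicates)",
                                      x$n_replicates) else "(single dataset)",
      "\n")
  cat(sprintf("  KM    = %.4g +- %.2g uM\n", x$km, x$km_sd))
  cat(sprintf("  kcat  = %.4g +- %.2g 1/s  (Vmax = %.4g, [E] = %g uM)\n",
              x$kcat, x$kcat_sd, x$vmax, x$enzyme_conc))
  cat(sprintf("  kcat/KM = %.4g 1/(M s)\n", x$efficiency))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(km = object$km, vmax = object$vmax, kcat = object$kcat)
}

#' @export
summary.mm_fit <- function(object, ...) {
  data.frame(parameter = c("KM_uM", "kcat_per_s", "efficiency_per_M_s"),
             estimate = c(object$km, object$kcat, object$efficiency),
             sd = c(object$km_sd, object$kcat_sd, NA))
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$substrate_uM else
    newdata$substrate_uM
  object$vmax * S / (object$km + S)
}

#' @export
plot.mm_fit <- function(x, ...) {
  S <- x$data$substrate_uM
  plot(S, x$data$rate, xlab = "[S] (uM)", ylab = "initial rate",
       main = "Michaelis-Menten fit", ...)
  ss <- seq(0, max(S), length.out = 200)
  lines(ss, x$vmax * ss / (x$km + ss))
  invisible(x)
}

#' Catalytic-efficiency ratio of two fits
#'
#' Ratio of `kcat/KM` efficiencies, reported raw and rounded to the nearest
#' integer.
#'
#' @param a,b `mm_fit` objects, or plain numeric efficiencies (1/(M s)).
#' @return list with `ratio` and `rounded`.
#' @export
efficiency_ratio <- function(a, b) {
  ea <- if (inherits(a, "mm_fit")) a$efficiency else as.numeric(a)
  eb <- if (inherits(b, "mm_fit")) b$efficiency else as.numeric(b)
  if (eb == 0) stop2("zero denominator efficiency")
  if (ea <= 0 || eb <= 0) stop2("efficiencies must be positive")
  r <- ea / eb
  list(ratio = r, rounded = round(r))
}

#' Relative activity table
#'
#' Specific activities expressed relative to a reference substrate
#' (`RA = 100 * activity / activity(reference)`), to 1 decimal.
#'
#' @param activities named numeric vector of specific activities
#'   (e.g. nmol/min/mg) keyed by substrate.
#' @param reference name of the reference substrate.
#' @return data.frame `substrate`, `activity`, `ra` with the reference at
#'   RA = 100.
#' @export
relative_activity <- function(activities, reference) {
  if (!reference %in% names(activities))
    stop2("reference substrate '", reference, "' not in table")
  ref <- activities[[reference]]
  if (ref <= 0) stop2("reference activity must be positive")
  data.frame(substrate = names(activities),
             activity = unname(activities),
             ra = round(100 * unname(activities) / ref, 1),
             stringsAsFactors = FALSE)
}

#' Thermal-inactivation profile
#'
#' Normalises residual activities to the highest value (= 100%) and locates
#' T50, the temperature of the first downward crossing of 50% residual
#' activity, by linear interpolation.  Profiles that never drop below 50%
#' have no T50.
#'
#' @param temperature temperatures, degrees C (>= 2 points).
#' @param activity residual activities (same length).
#' @param normalize rescale to max = 100 (default)?  Set `FALSE` when the
#'   values are already normalized percentages.
#' @return An `inactivation_profile`: list with `profile` (data.frame
#'   `temperature`, `activity`, `normalized`), `t50` (degrees C or `NA`) and
#'   `t50_defined`.
#' @export
inactivation_profile <- function(temperature, activity, normalize = TRUE) {
  if (length(temperature) < 2 || length(temperature) != length(activity))
    stop2("need >= 2 matched (temperature, activity) points")
  ord <- order(temperature)
  temperature <- temperature[ord]; activity <- activity[ord]
  norm <- if (normalize) 100 * activity / max(activity) else activity
  t50 <- NA_real_
  for (i in seq_len(length(norm) - 1)) {
    if (norm[i] >= 50 && norm[i + 1] < 50) {
      t50 <- temperature[i] + (norm[i] - 50) / (norm[i] - norm[i + 1]) *
        (temperature[i + 1] - temperature[i])
      break
    }
  }
  structure(list(profile = data.frame(temperature = temperature,
                                      activity = activity,
                                      normalized = norm),
                 t50 = t50, t50_defined = !is.na(t50)),
            class = "inactivation_profile")
}

#' @export
print.inactivation_profile <- function(x, ...) {
  cat("Thermal inactivation profile (normalized to max = 100%)\n")
  print(x$profile, row.names = FALSE)
  if (x$t50_defined) cat(sprintf("T50 = %.1f C\n", x$t50)) else
    cat("T50: no crossing below 50% in the measured range\n")
  invisible(x)
}

#' Optimum of a measured activity series
#'
#' Descriptive argmax of a measured series (e.g. temperature or pH optimum);
#' no model is fitted.
#'
#' @param x condition values (temperature, pH, ...).
#' @param activity measured activities.
#' @return the condition value with maximal activity.
#' @export
activity_optimum <- function(x, activity) {
  if (length(x) != length(activity) || !length(x))
    stop2("x and activity must be matched non-empty vectors")
  x[which.max(activity)]
}
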