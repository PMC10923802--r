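#' Rate extraction from fluorescence time courses
#'
#' Translation (eGFP, 35S-methionine incorporation) and degradation
#' (DQ-BSA dequenching) rates are slopes of the linear segment of an
#' intensity-time trace; securin-CFP degradation rates are decay constants
#' from a constrained exponential fit after background subtraction. Raw
#' rates are normalized within an egg batch to the 1x-extract rate, and the
#' figure-legend phi-power transforms convert between assay geometries
#' (substrate constant, substrate co-diluted, apparent bimolecular rate
#' constant).
#'
#' @name rates
NULL

default_window <- function(assay, t_range) {
  switch(assay,
    egfp = c(50, 120),
    dqbsa = c(25, 120),
    s35 = c(t_range[1], 75),
    abort(sprintf("No default window for assay '%s'; supply `window`.", assay))
  )
}

ols_slope <- function(t, y) {
  fit <- lm(y ~ t)
  s <- suppressWarnings(summary(fit)) # perfect fits are expected on clean traces
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    # constant window: the slope is exactly 0 and R^2 undefined
    return(list(slope = 0, se = 0, r2 = NA_real_))
  }
  list(slope = unname(coef(fit)[2]), se = s$coefficients[2, 2], r2 = s$r.squared)
}

#' Extract a rate as the slope of a linear segment
#'
#' Ordinary least-squares slope of intensity against time over a window.
#' The window can be given explicitly, taken from the assay default
#' (eGFP: 50-120 min; DQ-BSA: 25-120 min; 35S: start-75 min), or chosen
#' automatically (`window = "auto"`): windows of length >= 30 min are slid
#' in 5-min steps, the window maximizing R^2 wins, ties broken by longest
#' window then earliest start — a deterministic replacement for manual
#' segment curation.
#'
#' @param data a time-course tibble with columns `time_min` (strictly
#'   increasing, >= 10 points) and `intensity`; an `assay` column (or the
#'   `assay` argument) selects the default window.
#' @param window `NULL` (assay default), a numeric `c(lo, hi)` in minutes,
#'   or `"auto"`.
#' @param assay assay kind overriding the data column.
#' @return a one-row tibble: `slope_au_min`, `se`, `r2`, `window_lo`,
#'   `window_hi`, `n_points`, plus `assay` and `phi` when present.
#' @export
linear_rate <- function(data, window = NULL, assay = NULL) {
  if (!all(c("time_min", "intensity") %in% names(data))) {
    abort("`data` must have columns `time_min` and `intensity`.")
  }
  t <- data$time_min
  y <- data$intensity
  if (is.unsorted(t, strictly = TRUE)) abort("`time_min` must be strictly increasing.")
  if (length(t) < 10) abort("Need at least 10 time points for rate extraction.")
  assay <- assay %||% (if ("assay" %in% names(data)) data$assay[1] else NULL)
  t_range <- range(t)

  pick <- function(lo, hi) t >= lo - .tol & t <= hi + .tol

  if (identical(window, "auto")) {
    if (diff(t_range) < 30) abort("Auto window selection needs >= 30 min of data.")
    starts <- seq(t_range[1], t_range[2] - 30, by = 5)
    best <- NULL
    for (lo in starts) {
      for (hi in seq(lo + 30, t_range[2], by = 5)) {
        idx <- pick(lo, hi)
        if (sum(idx) < 3) next
        f <- ols_slope(t[idx], y[idx])
        # flat windows (undefined R^2) rank below any real fit
        score <- if (is.na(f$r2)) -1 else f$r2
        len <- hi - lo
        if (is.null(best) ||
            score > best$score + .tol ||
            (abs(score - best$score) <= .tol &&
             (len > best$len + .tol ||
              (abs(len - best$len) <= .tol && lo < best$lo - .tol)))) {
          best <- list(score = score, len = len, lo = lo, hi = hi, fit = f,
                       n = sum(idx))
        }
      }
    }
    if (is.null(best)) abort("Auto window selection found no fittable window.")
    win <- c(best$lo, best$hi)
    fit <- best$fit
    n_used <- best$n
  } else {
    win <- window %||% default_window(assay %||% "", t_range)
    if (win[1] < t_range[1] - .tol || win[2] > t_range[2] + .tol || win[1] >= win[2]) {
      abort(sprintf("Window [%g, %g] min lies outside the data span [%g, %g].",
                    win[1], win[2], t_range[1], t_range[2]))
    }
    idx <- pick(win[1], win[2])
    if (sum(idx) < 3) abort("Fewer than 3 points fall inside the window.")
    fit <- ols_slope(t[idx], y[idx])
    n_used <- sum(idx)
  }
  if (is.na(fit$r2)) {
    warn("All intensities equal inside the window; slope is 0.")
  }
  tibble::tibble(
    slope_au_min = fit$slope, se = fit$se, r2 = fit$r2,
    window_lo = win[1], window_hi = win[2], n_points = n_used,
    assay = assay %||% NA_character_,
    phi = if ("phi" %in% names(data)) data$phi[1] else NA_real_
  )
}

#' Securin-CFP decay rate by constrained exponential fit
#'
#' Subtracts the background trace pointwise, divides by the maximum of the
#' first 15 time points (7.5 min at 2 samples/min — the early points can
#' rise while the fluorophore equilibrates), then fits
#' `A = A0 * exp(-k * t) + C` by bounded nonlinear least squares with
#' `A0` constrained to (0.95, 1.2], `C` to [0, 0.05], and `k` to [0, 10]
#' per minute. The fit starts at that early maximum with time re-zeroed
#' there, so pre-equilibration points do not bias the decay constant.
#' Parameters landing on a bound are flagged.
#'
#' @param data a securin time-course tibble with columns `time_min` and
#'   `intensity` (>= 15 points); a `background_intensity` column is used
#'   when `background` is not given.
#' @param background the background trace: a numeric vector (length 1 or
#'   matching the data) or a tibble with `intensity` on the same grid.
#'   Defaults to the `background_intensity` column, else 0.
#' @return a `securin_fit` with fields `A0`, `k`, `C`, `se_k`,
#'   `at_bound` (named logical), `converged`.
#' @export
securin_decay_rate <- function(data, background = NULL) {
  if (!all(c("time_min", "intensity") %in% names(data))) {
    abort("`data` must have columns `time_min` and `intensity`.")
  }
  t <- data$time_min
  y <- data$intensity
  if (length(t) < 15) abort("Need at least 15 time points (7.5 min at 2/min).")
  bg <- if (!is.null(background)) {
    if (is.data.frame(background)) {
      if (nrow(background) != length(y)) abort("Background grid does not match the data.")
      background$intensity
    } else background
  } else if ("background_intensity" %in% names(data)) {
    data$background_intensity
  } else 0
  if (!(length(bg) %in% c(1L, length(y)))) {
    abort("Background must have length 1 or match the data.")
  }
  corrected <- y - bg
  i_max <- which.max(corrected[seq_len(15)])
  norm_const <- corrected[i_max]
  if (!is.finite(norm_const) || norm_const <= 0) {
    abort("Normalization constant (max of first 15 points) must be positive.")
  }
  # fit from the early maximum onward, time re-zeroed there, so the
  # equilibration rise does not distort the decay
  tt <- t[i_max:length(t)] - t[i_max]
  A <- corrected[i_max:length(t)] / norm_const

  lower <- c(A0 = 0.95, k = 0, C = 0)
  upper <- c(A0 = 1.2, k = 10, C = 0.05)
  # self-starting guess for k from the time at which A first halves
  t_half <- tt[which(A <= 0.5)[1]]
  k0 <- if (is.na(t_half) || t_half <= 0) 0.05 else log(2) / t_half
  k0 <- min(max(k0, 1e-4), 9)
  res_fun <- function(p) A - (p[["A0"]] * exp(-p[["k"]] * tt) + p[["C"]])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A0 = 1, k = k0, C = 0.01), fn = res_fun,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      abort(paste0("Securin fit did not converge: ", conditionMessage(e),
                   " (start: A0=1, k=", signif(k0, 3), ", C=0.01)"))
    }
  )
  if (fit$info %in% c(0, 5)) {
    abort(paste0("Securin fit did not converge: ", fit$message,
                 " (start: A0=1, k=", signif(k0, 3), ", C=0.01)"))
  }
  est <- fit$par
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients[, 2]),
    error = function(e) rep(NA_real_, 3)
  )
  btol <- 1e-6
  at_bound <- c(
    A0 = est[["A0"]] <= lower[["A0"]] + btol || est[["A0"]] >= upper[["A0"]] - btol,
    k = est[["k"]] >= upper[["k"]] - btol,
    C = est[["C"]] <= lower[["C"]] + btol || est[["C"]] >= upper[["C"]] - btol
  )
  if (at_bound[["A0"]] && at_bound[["C"]]) {
    warn("Securin fit pinned both A0 and C at their bounds; inspect the trace.")
  }
  structure(list(
    A0 = est[["A0"]], k = est[["k"]], C = est[["C"]],
    se_k = unname(se[2]), at_bound = at_bound, converged = TRUE,
    norm_const = norm_const
  ), class = "securin_fit")
}

#' @export
print.securin_fit <- function(x, ...) {
  cat("<securin_fit>  A = A0 * exp(-k t) + C\n")
  cat(sprintf("  A0 = %.4f  k = %.5g /min (se %.3g)  C = %.4f\n",
              x$A0, x$k, x$se_k, x$C))
  if (any(x$at_bound)) {
    cat("  at bound:", paste(names(x$at_bound)[x$at_bound], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.securin_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A0", "k", "C"),
    estimate = c(x$A0, x$k, x$C),
    std.error = c(NA_real_, x$se_k, NA_real_),
    at_bound = unname(x$at_bound)
  )
}

#' Normalize rates to the 1x reference within each batch
#'
#' Divides every rate by the mean rate measured at `phi = reference_phi` in
#' the same batch (egg batches vary, so normalization is within-batch). If
#' the data carry no `batch` column, all rows form one batch.
#'
#' @param data a tibble with columns `phi`, `rate`, optionally `batch`.
#' @param reference_phi the reference concentration (default 1).
#' @return the input with a `normalized_rate` column appended.
#' @export
normalize_rates <- function(data, reference_phi = 1) {
  if (!all(c("phi", "rate") %in% names(data))) {
    abort("`data` must have columns `phi` and `rate`.")
  }
  has_batch <- "batch" %in% names(data)
  grouped <- if (has_batch) dplyr::group_by(data, .data$batch) else data
  out <- dplyr::mutate(grouped, normalized_rate = {
    ref <- .data$rate[abs(.data$phi - reference_phi) < .tol]
    if (length(ref) == 0) {
      abort(sprintf("No reference measurement at phi = %g in %s.",
                    reference_phi,
                    if (has_batch) paste0("batch '", dplyr::cur_group()$batch, "'")
                    else "the data"))
    }
    .data$rate / mean(ref)
  })
  dplyr::ungroup(out)
}

#' Power-of-phi rate transforms
#'
#' Converts between assay geometries by multiplying a measured rate by
#' `phi^p`: `p = +1` infers rates for an endogenous substrate co-diluted
#' with the machinery, `p = -1` the apparent bimolecular rate constant,
#' `p = -2` the double concentration correction used for 35S incorporation,
#' `p = 0` the identity.
#'
#' @param rate measured rate(s).
#' @param phi relative cytoplasmic concentration(s); must be > 0 for
#'   negative powers.
#' @param power one of -2, -1, 0, +1.
#' @return transformed rate(s).
#' @export
transform_rate <- function(rate, phi, power) {
  if (!power %in% c(-2, -1, 0, 1)) abort("`power` must be one of -2, -1, 0, +1.")
  if (power < 0 && any(phi <= 0)) abort("`phi` must be > 0 for negative powers.")
  rate * phi^power
}

#' One-tailed paired t-test
#'
#' Tests whether `mean(x) > mean(y)` for paired observations, returning the
#' one-tailed p-value. Degenerate pairs with zero difference variance return
#' 0.5 (no evidence either way), 0 or 1 according to the sign of the mean
#' difference.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return the one-tailed p-value.
#' @export
paired_one_tailed_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must be paired vectors of equal length >= 2.")
  }
  d <- x - y
  if (sd(d) == 0) {
    return(if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5)
  }
  unname(t.test(x, y, paired = TRUE, alternative = "greater")$p.value)
}
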