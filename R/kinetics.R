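#' Enzyme kinetic model
#'
#' Michaelis-Menten kinetics with optional uncompetitive substrate
#' inhibition. Either `Vmax` or the pair (`kcat`, `E0`) must be given;
#' `Vmax = kcat * E0`. `Ki = Inf` (the default) disables inhibition.
#'
#' @param Vmax Maximal velocity, mM/s.
#' @param Km Michaelis constant, mM (> 0).
#' @param Ki Substrate-inhibition constant, mM (> 0, `Inf` for none).
#' @param kcat Turnover number, 1/s (alternative to `Vmax`).
#' @param E0 Enzyme concentration, mM (required with `kcat`).
#' @return List of class `kinetic_model`.
#' @export
kinetic_model <- function(Vmax = NULL, Km, Ki = Inf, kcat = NULL,
                          E0 = NULL) {
  if (is.null(Vmax)) {
    if (is.null(kcat) || is.null(E0))
      stop("supply either Vmax or both kcat and E0", call. = FALSE)
    Vmax <- kcat * E0
  }
  assert_scalar_number(Km, "Km", min = 0, strict = TRUE)
  assert_scalar_number(Vmax, "Vmax", min = 0)
  if (!is.infinite(Ki)) assert_scalar_number(Ki, "Ki", min = 0,
                                             strict = TRUE)
  structure(list(Vmax = Vmax, Km = Km, Ki = Ki, kcat = kcat, E0 = E0),
            class = "kinetic_model")
}

#' Reaction velocity under a kinetic model
#'
#' `v = Vmax * S / (Km + S * (1 + S / Ki))`; with `Ki = Inf` this is the
#' Michaelis-Menten hyperbola `Vmax * S / (Km + S)`. With finite `Ki` the
#' curve peaks at `S = sqrt(Km * Ki)` and declines at higher substrate
#' (substrate inhibition).
#'
#' @param S Substrate concentration(s), mM (>= 0).
#' @param model A [kinetic_model()].
#' @return Velocity v in the units of `Vmax`.
#' @export
velocity <- function(S, model) {
  if (any(S < 0)) stop("'S' must be non-negative", call. = FALSE)
  model$Vmax * S / (model$Km + S * (1 + S / model$Ki))
}

#' Nessler assay calibration
#'
#' Molar absorption coefficient of the Nessler reaction product at
#' 480 nm (default 1302 1/(M cm)) and optical path length.
#'
#' @param epsilon_480 Molar absorption coefficient, 1/(M cm).
#' @param path_length Cuvette path length, cm.
#' @return List of class `assay_calibration`.
#' @export
assay_calibration <- function(epsilon_480 = 1302, path_length = 1) {
  assert_scalar_number(epsilon_480, "epsilon_480", min = 0, strict = TRUE)
  assert_scalar_number(path_length, "path_length", min = 0, strict = TRUE)
  structure(list(epsilon_480 = epsilon_480, path_length = path_length),
            class = "assay_calibration")
}

#' Convert Nessler absorbance to ammonia concentration
#'
#' Beer-Lambert inversion `c = A / (epsilon * l)`, reported in mM.
#'
#' @param A480 Absorbance at 480 nm (>= 0).
#' @param calib An [assay_calibration()].
#' @return Ammonia concentration, mM.
#' @examples
#' absorbance_to_ammonia(1.302)  # 1 mM
#' @export
absorbance_to_ammonia <- function(A480, calib = assay_calibration()) {
  if (any(A480 < 0)) stop("absorbance must be non-negative", call. = FALSE)
  1000 * A480 / (calib$epsilon_480 * calib$path_length)
}

new_kinetic_fit <- function(model, method, residuals, excluded, failed,
                            converged = TRUE) {
  structure(list(model = model, method = method,
                 residuals = residuals, excluded = excluded,
                 failed = failed, converged = converged),
            class = "kinetic_fit")
}

#' Lineweaver-Burk (double-reciprocal) kinetic fit
#'
#' Ordinary least squares of `1/v` on `1/S`; `Km = slope / intercept`,
#' `Vmax = 1 / intercept`. Points with substrate above `S_max` are
#' excluded by default because substrate inhibition above ~5 mM bends the
#' double-reciprocal plot away from the Michaelis-Menten line; zero
#' velocities are excluded with a warning. An optional blank-rate column
#' `blank` in the dataset is subtracted from `v` before fitting. When the
#' enzyme concentration is known (argument or dataset attribute `E0`),
#' the turnover number `kcat = Vmax / E0` is reported.
#'
#' @param dataset Data frame with columns `S_mM` and `v` (and optionally
#'   `blank`), e.g. from [make_kinetic_dataset()].
#' @param S_max Inclusion cutoff on substrate concentration, mM (default
#'   5; `Inf` to use all points).
#' @param E0 Enzyme concentration, mM.
#' @return A `kinetic_fit`: fitted [kinetic_model()] (with `kcat` when
#'   `E0` is known), `method = "LB"`, residual summary on the reciprocal
#'   axes, excluded row indices, `failed` flag (non-positive intercept).
#' @export
fit_lineweaver_burk <- function(dataset, S_max = 5, E0 = NULL) {
  E0 <- E0 %||% attr(dataset, "E0")
  v <- dataset$v
  if (!is.null(dataset$blank)) v <- v - dataset$blank
  drop_zero <- which(v <= 0)
  if (length(drop_zero))
    warning("excluding ", length(drop_zero), " point(s) with v <= 0")
  drop_s <- which(dataset$S_mM > S_max)
  excluded <- sort(union(drop_zero, drop_s))
  keep <- setdiff(seq_len(nrow(dataset)), excluded)
  if (length(keep) < 3)
    stop("need at least 3 points with S <= S_max and v > 0",
         call. = FALSE)
  fit <- lm(I(1 / v[keep]) ~ I(1 / dataset$S_mM[keep]))
  ic <- coef(fit)[[1]]; sl <- coef(fit)[[2]]
  if (ic <= 0) {
    warning("non-positive intercept; Lineweaver-Burk fit failed")
    return(new_kinetic_fit(NULL, "LB", summary(fit)$sigma, excluded,
                           failed = TRUE))
  }
  Vmax <- 1 / ic
  Km <- sl / ic
  model <- kinetic_model(Vmax = Vmax, Km = Km, Ki = Inf)
  if (!is.null(E0)) model$kcat <- Vmax / E0
  new_kinetic_fit(model, "LB", summary(fit)$sigma, excluded,
                  failed = FALSE)
}

#' Nonlinear least-squares kinetic fit
#'
#' Fits [velocity()] directly to (S, v) data by Levenberg-Marquardt
#' minimisation, with or without the substrate-inhibition term. Starting
#' values: `Vmax` from the largest observed velocity, `Km` from the
#' substrate at half-maximal velocity, `Ki` from five times the largest
#' substrate concentration. On non-convergence the best iterate is
#' returned with `converged = FALSE`.
#'
#' @param dataset Data frame with `S_mM` and `v` (optional `blank`
#'   subtracted first).
#' @param with_inhibition Fit the substrate-inhibition constant Ki
#'   (`TRUE`) or the plain Michaelis-Menten model (`FALSE`, default).
#' @param E0 Enzyme concentration, mM, to report `kcat`.
#' @param start Optional named list overriding the starting values.
#' @return A `kinetic_fit` with `method = "NLS"` and the residual
#'   standard deviation on the velocity axis.
#' @export
fit_nonlinear <- function(dataset, with_inhibition = FALSE, E0 = NULL,
                          start = NULL) {
  E0 <- E0 %||% attr(dataset, "E0")
  v <- dataset$v
  if (!is.null(dataset$blank)) v <- v - dataset$blank
  keep <- which(v > 0 & dataset$S_mM > 0)
  S <- dataset$S_mM[keep]; vv <- v[keep]
  need <- if (with_inhibition) 5L else 4L
  if (length(keep) < need)
    stop("need at least ", need, " positive-velocity points", call. = FALSE)
  Vmax0 <- start$Vmax %||% max(vv)
  Km0 <- start$Km %||% S[which.min(abs(vv - Vmax0 / 2))]
  df <- data.frame(S = S, v = vv)
  fit <- tryCatch({
    if (with_inhibition) {
      Ki0 <- start$Ki %||% (5 * max(S))
      minpack.lm::nlsLM(v ~ Vmax * S / (Km + S * (1 + S / Ki)), data = df,
                        start = list(Vmax = Vmax0, Km = max(Km0, 1e-6),
                                     Ki = Ki0),
                        lower = c(0, 1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                        start = list(Vmax = Vmax0, Km = max(Km0, 1e-6)),
                        lower = c(0, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)
  if (inherits(fit, "error"))
    return(new_kinetic_fit(NULL, "NLS", NA_real_,
                           setdiff(seq_len(nrow(dataset)), keep),
                           failed = TRUE, converged = FALSE))
  cf <- coef(fit)
  model <- kinetic_model(Vmax = cf[["Vmax"]], Km = cf[["Km"]],
                         Ki = if (with_inhibition) cf[["Ki"]] else Inf)
  if (!is.null(E0)) model$kcat <- model$Vmax / E0
  new_kinetic_fit(model, "NLS",
                  sqrt(mean(stats::residuals(fit)^2)),
                  setdiff(seq_len(nrow(dataset)), keep), failed = FALSE,
                  converged = fit$convInfo$isConv %||% TRUE)
}

#' Relative activity of an enzyme variant
#'
#' `100 * variant_rate / wt_rate`, with values below the detection floor
#' (default 0.1% of wild type, i.e. a turnover number three orders of
#' magnitude below wild type) reported as 0 -- such variants are deemed
#' inactive.
#'
#' @param variant_rate,wt_rate Non-negative rates in the same units
#'   (`wt_rate > 0`).
#' @param floor Detection floor in percent (default 0.1).
#' @return Relative activity, percent.
#' @export
relative_activity <- function(variant_rate, wt_rate, floor = 0.1) {
  if (any(variant_rate < 0) || any(wt_rate <= 0))
    stop("rates must be non-negative and wt_rate positive", call. = FALSE)
  pct <- 100 * variant_rate / wt_rate
  ifelse(pct < floor, 0, pct)
}

#' pH optimum of an activity profile
#'
#' Returns the grid point of maximal mean activity. Ties are broken
#' towards the lower pH and flagged; an optimum at either end of the
#' grid is flagged as a boundary (the true optimum may lie outside the
#' assayed range).
#'
#' @param profile Data frame with columns `pH` and `activity` (replicates
#'   allowed; averaged per pH).
#' @return List with `ph_optimum`, `activity`, `tie`, `at_boundary`.
#' @export
ph_optimum <- function(profile) {
  if (is.null(profile) || nrow(profile) < 2)
    stop("profile must contain at least 2 points", call. = FALSE)
  agg <- aggregate(activity ~ pH, data = profile, FUN = mean)
  agg <- agg[order(agg$pH), ]
  mx <- max(agg$activity)
  at <- which(agg$activity == mx)
  list(ph_optimum = agg$pH[at[1]], activity = mx,
       tie = length(at) > 1L,
       at_boundary = at[1] %in% c(1L, nrow(agg)))
}
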