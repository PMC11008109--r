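# Correlogram I/O, synthetic-curve generation and weighted nonlinear
# least-squares fitting of any engine model to experimental correlograms.

#' Correlation curve container
#'
#' A measured or synthetic FCS correlogram: strictly increasing positive
#' lag times, correlation values, optional per-point standard errors and
#' free-form acquisition metadata.
#'
#' @param lag lag times (s), strictly increasing, `> 0` (a leading 0 is
#'   allowed for model curves).
#' @param g correlation values.
#' @param sigma optional standard errors (`> 0`).
#' @param meta named list of metadata.
#' @return data frame of class `fcs_curve` with columns `lag`, `g` and
#'   optionally `sigma`; metadata in `attr(, "meta")`.
#' @export
fcs_curve <- function(lag, g, sigma = NULL, meta = list()) {
  if (length(lag) != length(g)) stop("'lag' and 'g' must have equal length")
  if (length(lag) == 0L) stop("empty curve")
  if (any(!is.finite(lag)) || any(!is.finite(g)))
    stop("nonfinite values in curve")
  if (any(lag < 0) || any(diff(lag) <= 0))
    stop("'lag' must be nonnegative and strictly increasing")
  out <- data.frame(lag = lag, g = g)
  if (!is.null(sigma)) {
    if (length(sigma) != length(lag)) stop("'sigma' length mismatch")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("'sigma' must be positive")
    out$sigma <- sigma
  }
  attr(out, "meta") <- meta
  class(out) <- c("fcs_curve", class(out))
  out
}

#' Read a correlogram from delimited text
#'
#' Expects whitespace- or comma-delimited columns `lag_s`, `G` and
#' optionally `sigma`; lines starting with `#` are comments (those of the
#' form `# key: value` are collected into the metadata).  Malformed or
#' nonmonotone rows are rejected with their line numbers.
#'
#' @param path file path.
#' @return an [fcs_curve].
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  meta <- list()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", cl))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  data_idx <- which(!is_comment & !is_blank)
  if (length(data_idx) == 0L) stop("no data rows in ", path)
  first <- strsplit(trimws(lines[data_idx[1]]), "[,[:space:]]+")[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  if (has_header) data_idx <- data_idx[-1]
  if (length(data_idx) == 0L)
    stop("header-only file (no data rows) in ", path)
  rows <- lapply(data_idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || length(vals) > 3L || any(is.na(vals)))
      stop(sprintf("malformed row at line %d of %s: '%s'", i, path, lines[i]))
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("inconsistent column count at line %d of %s",
                 data_idx[which(ncols != ncols[1])[1]], path))
  m <- do.call(rbind, rows)
  bad <- which(diff(m[, 1]) <= 0)
  if (length(bad) > 0L)
    stop(sprintf("nonmonotone lag at line %d of %s", data_idx[bad[1] + 1], path))
  fcs_curve(lag = m[, 1], g = m[, 2],
            sigma = if (ncol(m) == 3L) m[, 3] else NULL, meta = meta)
}

#' Write a correlogram as delimited text
#'
#' Inverse of [read_curve()]: metadata as `# key: value` comments, a header
#' row, then whitespace-delimited `lag_s G [sigma]` rows at full double
#' precision (lossless round trip).
#'
#' @param curve an [fcs_curve].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_curve"))
  meta <- attr(curve, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  has_sigma <- "sigma" %in% names(curve)
  writeLines(if (has_sigma) "lag_s G sigma" else "lag_s G", con)
  fmt <- function(v) sprintf("%.17g", v)
  body <- if (has_sigma)
    paste(fmt(curve$lag), fmt(curve$g), fmt(curve$sigma))
  else paste(fmt(curve$lag), fmt(curve$g))
  writeLines(body, con)
  invisible(path)
}

#' Generate a synthetic correlogram
#'
#' Engine curve on a log-spaced lag grid plus reproducible pseudo-random
#' noise.  `proportional` noise multiplies the curve by `1 + c * N(0,1)`
#' and records `sigma = c * G`; `additive` adds `s * N(0,1)` with constant
#' `sigma = s`.  The seed fully determines the output.
#'
#' @param params an [fcs_params] object.
#' @param method engine route (see [full_acf()]).
#' @param noise one of `"none"`, `"proportional"`, `"additive"`.
#' @param noise_level the constant `c` or `s` above.
#' @param seed integer seed (required when noise is not `"none"`).
#' @param n number of lag points.
#' @param tmin,tmax grid limits in units of `tau_B`.
#' @return an [fcs_curve]; generation settings in the metadata.
#' @export
synthesize_curve <- function(params, method = "moment_expansion",
                             noise = c("none", "proportional", "additive"),
                             noise_level = 0.01, seed = NULL, n = 128L,
                             tmin = 1e-2, tmax = 1e3) {
  noise <- match.arg(noise)
  stopifnot(inherits(params, "fcs_params"))
  t_grid <- params$diffusion$tau_B *
    10^seq(log10(tmin), log10(tmax), length.out = n)
  base <- full_acf(t_grid, params, method = method)
  g <- base$g
  sigma <- NULL
  if (noise != "none") {
    if (is.null(seed)) stop("a seed is required for noisy synthesis")
    set.seed(seed)
    if (noise == "proportional") {
      g <- g * (1 + noise_level * stats::rnorm(n))
      sigma <- noise_level * base$g
    } else {
      g <- g + noise_level * stats::rnorm(n)
      sigma <- rep(noise_level, n)
    }
  }
  fcs_curve(lag = t_grid, g = g, sigma = sigma,
            meta = list(method = method, noise = noise,
                        noise_level = if (noise == "none") 0 else noise_level,
                        seed = if (is.null(seed)) NA else seed))
}

# Fit parameterisation.  Natural parameters and their unconstrained
# transforms: log for positive-definite quantities, logit for beta,
# log for tau_ratio (positive, bounded checks applied on the natural
# scale).  beta and R are the internal reaction coordinates; k23 = R*beta
# and k32 = R*(1-beta) are derived on report.
FIT_PARAMS <- c("tau_B", "tau_ratio", "beta", "R", "N1", "N23", "Q_B", "Q_C")

fit_transform <- function(theta) {
  tr <- theta
  for (nm in names(theta)) {
    tr[[nm]] <- if (nm == "beta") stats::qlogis(theta[[nm]]) else log(theta[[nm]])
  }
  tr
}

fit_untransform <- function(tr) {
  th <- tr
  for (nm in names(tr)) {
    th[[nm]] <- if (nm == "beta") stats::plogis(tr[[nm]]) else exp(tr[[nm]])
  }
  th
}

fit_params_from_theta <- function(theta, omega) {
  v <- (1 / theta[["beta"]] + theta[["tau_ratio"]] / (1 - theta[["beta"]])) /
    (theta[["R"]] * theta[["tau_B"]])
  fcs_params_dimensionless(tau_ratio = theta[["tau_ratio"]],
                           beta = theta[["beta"]], v = v,
                           omega = omega, tau_B = theta[["tau_B"]],
                           N1 = theta[["N1"]], N23 = theta[["N23"]],
                           Q_B = theta[["Q_B"]], Q_C = theta[["Q_C"]])
}

#' Fit an engine model to a correlogram
#'
#' Weighted nonlinear least squares (weights `1/sigma^2` when the curve
#' carries standard errors, else uniform) of any engine route to a measured
#' or synthetic curve.  The fit runs in unconstrained coordinates (log for
#' positive parameters, logit for `beta`; `beta` and `R` instead of the
#' strongly correlated `k23`, `k32`) with multi-start: `n_starts` seeded
#' log-normal perturbations of the initial guess, keeping the best
#' converged result.  Any subset of parameters can be held fixed (e.g. a
#' dye diffusion coefficient known from calibration).  Asymptotic standard
#' errors come from the Gauss-Newton approximation at the optimum;
#' parameters whose log-scale uncertainty exceeds 1 are flagged
#' non-identifiable.
#'
#' @param curve an [fcs_curve].
#' @param model_method engine route used as the fit model (default
#'   `"moment_expansion"`, the closed form).
#' @param initial named list of starting values for the free parameters
#'   among `tau_B`, `tau_ratio`, `beta`, `R`, `N1`, `N23`, `Q_B`, `Q_C`.
#' @param fixed named list of parameters held constant (must cover the
#'   complement of `initial`).
#' @param omega focal-volume aspect ratio (fixed, not fitted).
#' @param n_starts number of multi-start restarts.
#' @param start_sd standard deviation (transformed scale) of the seeded
#'   log-normal perturbations applied to the restart initials.
#' @param seed seed for the restart perturbations.
#' @return object of class `fcs_fit`: `estimates` (including derived `k23`,
#'   `k32`, `v`), `stderr`, `fixed`, `chi2_red`, `converged`, `method`,
#'   `nonidentifiable`, plus per-restart diagnostics.
#' @export
fit_acf <- function(curve, model_method = "moment_expansion",
                    initial, fixed = list(), omega = 5,
                    n_starts = 8L, start_sd = 0.2, seed = 1L) {
  stopifnot(inherits(curve, "fcs_curve"))
  initial <- unlist(initial)
  fixed <- unlist(fixed)
  if (length(initial) == 0L) stop("at least one free parameter is required")
  if (!all(names(initial) %in% FIT_PARAMS) ||
      (length(fixed) && !all(names(fixed) %in% FIT_PARAMS)))
    stop("parameters must be among: ", paste(FIT_PARAMS, collapse = ", "))
  missing <- setdiff(FIT_PARAMS, c(names(initial), names(fixed)))
  if (length(missing) > 0L)
    stop("no value for parameter(s): ", paste(missing, collapse = ", "))
  free <- names(initial)
  w <- if ("sigma" %in% names(curve)) 1 / curve$sigma^2 else rep(1, nrow(curve))
  lag <- curve$lag
  gobs <- curve$g

  obj <- function(tr_free) {
    theta <- c(fit_untransform(as.list(tr_free)), as.list(fixed))
    p <- tryCatch(fit_params_from_theta(theta, omega), error = function(e) NULL)
    if (is.null(p)) return(1e12)
    gm <- tryCatch(full_acf(lag, p, method = model_method)$g,
                   error = function(e) NULL)
    if (is.null(gm) || any(!is.finite(gm))) return(1e12)
    sum(w * (gobs - gm)^2)
  }

  tr0 <- unlist(fit_transform(as.list(initial)))
  set.seed(seed)
  runs <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    start <- if (k == 1L) tr0 else tr0 + stats::rnorm(length(tr0), 0, start_sd)
    fit <- tryCatch(stats::optim(start, obj, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    runs[[k]] <- fit
  }
  ok <- !vapply(runs, is.null, logical(1))
  vals <- vapply(runs, function(r) if (is.null(r)) Inf else r$value, numeric(1))
  conv <- vapply(runs, function(r) !is.null(r) && r$convergence == 0, logical(1))
  if (!any(ok))
    stop("no restart converged; per-restart values: ",
         paste(format(vals), collapse = ", "))
  best <- runs[[which.min(vals)]]
  tr_hat <- best$par
  theta_hat <- fit_untransform(as.list(tr_hat))

  # Gauss-Newton covariance in transformed coordinates
  model_at <- function(tr_free) {
    theta <- c(fit_untransform(as.list(tr_free)), as.list(fixed))
    full_acf(lag, fit_params_from_theta(theta, omega), method = model_method)$g
  }
  g_hat <- model_at(tr_hat)
  J <- matrix(NA_real_, length(lag), length(tr_hat))
  h <- 1e-5
  for (j in seq_along(tr_hat)) {
    up <- tr_hat; up[j] <- up[j] + h
    dn <- tr_hat; dn[j] <- dn[j] - h
    J[, j] <- (model_at(up) - model_at(dn)) / (2 * h)
  }
  dof <- max(length(lag) - length(tr_hat), 1L)
  chi2_red <- sum(w * (gobs - g_hat)^2) / dof
  JtWJ <- crossprod(J * sqrt(w))
  # scale by chi2_red in both weighting conventions: with unit weights it is
  # the residual variance estimate, with stated sigma it guards against
  # over- or under-stated uncertainties
  cov_tr <- tryCatch(solve(JtWJ) * chi2_red,
                     error = function(e) matrix(NA_real_, length(tr_hat), length(tr_hat)))
  se_tr <- sqrt(pmax(diag(cov_tr), 0))
  names(se_tr) <- free

  # A locally well-conditioned Hessian can still hide a direction that is
  # flat at the noise scale (e.g. the reaction rate on effective-diffusion
  # data, where every large R produces the same curve): probe each free
  # parameter three log-units away from the optimum and call the direction
  # flat if the objective rises by less than a 95% chi-square step.  Flat
  # directions get their transformed-scale uncertainty floored at the probe
  # distance, so the reported standard error exceeds the estimate.
  flat <- logical(length(tr_hat))
  for (j in seq_along(tr_hat)) {
    for (sgn in c(-1, 1)) {
      probe <- tr_hat
      probe[j] <- probe[j] + 3 * sgn
      dinc <- obj(probe) - best$value
      if (is.finite(dinc) && dinc < 1e11 &&
          dinc < 3.84 * max(chi2_red, 1e-12)) flat[j] <- TRUE
    }
  }
  se_tr <- ifelse(flat, pmax(ifelse(is.finite(se_tr), se_tr, 0), 3), se_tr)
  names(se_tr) <- free

  # delta method back to natural scale
  est <- unlist(theta_hat)[free]
  se_nat <- se_tr * ifelse(free == "beta", est * (1 - est), est)

  # derived reaction rates and their errors
  derived <- derive_rates(theta_hat, fixed, free, cov_tr)

  structure(list(
    estimates = c(est, derived$est),
    stderr = c(se_nat, derived$se),
    fixed = fixed,
    chi2_red = chi2_red,
    converged = conv[which.min(vals)],
    n_converged = sum(conv),
    method = model_method,
    nonidentifiable = free[flat | (is.finite(se_tr) & se_tr > 1)],
    restart_values = vals,
    curve_fit = fcs_curve(lag, g_hat)), class = "fcs_fit")
}

# k23 = R*beta, k32 = R*(1-beta), v: delta-method errors from the
# transformed-coordinate covariance of the free parameters.
derive_rates <- function(theta_hat, fixed, free, cov_tr) {
  th <- c(theta_hat, as.list(fixed))
  R <- th[["R"]]; beta <- th[["beta"]]
  est <- c(k23 = R * beta, k32 = R * (1 - beta))
  # gradients w.r.t. (log R, logit beta)
  grads <- list(
    k23 = c(R = R * beta, beta = R * beta * (1 - beta)),
    k32 = c(R = R * (1 - beta), beta = -R * beta * (1 - beta)))
  se <- vapply(names(grads), function(nm) {
    g <- grads[[nm]][intersect(c("R", "beta"), free)]
    if (length(g) == 0L) return(0)
    idx <- match(names(g), free)
    sqrt(max(t(g) %*% cov_tr[idx, idx, drop = FALSE] %*% g, 0))
  }, numeric(1))
  list(est = est, se = se)
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("FCS model fit (", x$method, ")\n", sep = "")
  tab <- data.frame(estimate = x$estimates,
                    stderr = x$stderr[names(x$estimates)])
  print(format(tab, digits = 5))
  cat(sprintf("reduced chi-square: %.4g; converged: %s (%d/%d restarts)\n",
              x$chi2_red, x$converged, x$n_converged,
              length(x$restart_values)))
  if (length(x$nonidentifiable))
    cat("non-identifiable parameters:",
        paste(x$nonidentifiable, collapse = ", "), "\n")
  invisible(x)
}
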