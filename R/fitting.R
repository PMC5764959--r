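# Response datasets, synthetic data generation and nonlinear
# least-squares fitting for the ligand-response models.

MODEL_TAGS <- c("hill", "titration", "mst", "itc", "transient")

#' Response dataset
#'
#' An (x, y, sigma) dataset tagged with the model it describes: `"hill"`
#' (concentration in mM vs normalized current), `"titration"` (pH vs
#' normalized current), `"mst"` (ligand in micromolar vs normalized
#' signal), `"itc"` (injection index vs kcal/mol of injectant; the cell
#' geometry travels in `meta`) or `"transient"` (time in ms vs current in
#' nA).
#'
#' @param x Abscissa values, strictly increasing for titrations.
#' @param y Responses, same length.
#' @param sigma Optional per-point uncertainties, `> 0`.
#' @param model One of `"hill"`, `"titration"`, `"mst"`, `"itc"`,
#'   `"transient"`.
#' @param meta Named list of auxiliary constants (for `"itc"`:
#'   `cell_conc`, `cell_vol`, `inj_vol`, `syringe_conc`).
#' @return Object of class `response_dataset`.
#' @export
response_dataset <- function(x, y, sigma = NULL, model, meta = list()) {
  model <- match.arg(model, MODEL_TAGS)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (!is.null(sigma)) {
    if (length(sigma) == 1) sigma <- rep(sigma, length(x))
    if (length(sigma) != length(x) || any(sigma <= 0))
      stop("sigma must be positive, one per point")
  }
  if (model %in% c("hill", "titration", "mst") && any(diff(x) <= 0))
    stop("titration abscissa must be strictly increasing")
  structure(list(x = x, y = y, sigma = sigma, model = model, meta = meta),
            class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(sprintf("response_dataset (%s): %d points, x in [%.4g, %.4g]%s\n",
              x$model, length(x$x), min(x$x), max(x$x),
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  invisible(x)
}

model_fun <- function(model, meta = list()) {
  switch(model,
    hill = function(x, p) hill_response(x, p[["i_max"]], p[["k05"]], p[["h"]]),
    titration = function(x, p)
      titration_response(x, p[["i_min"]], p[["i_max"]], p[["pk_app"]], p[["n"]]),
    mst = function(x, p) binding_isotherm(x, p[["f_free"]], p[["f_bound"]], p[["k_d"]]),
    itc = function(x, p)
      itc_injection_heats(p[["n"]], p[["k_d"]], p[["dh"]],
                          meta$cell_conc, meta$cell_vol, meta$inj_vol,
                          meta$syringe_conc, length(x))[x],
    stop("no parametric model for tag '", model, "'"))
}

#' Generate a synthetic response dataset
#'
#' Evaluates the tagged model on a design and adds Gaussian noise of
#' standard deviation `noise`; reproducible by seed.
#'
#' @param model Model tag (see [response_dataset()]).
#' @param params Named list/vector of model parameters (`hill`: `i_max,
#'   k05, h`; `titration`: `i_min, i_max, pk_app, n`; `mst`: `f_free,
#'   f_bound, k_d`; `itc`: `n, k_d, dh`).
#' @param x Design points (for `"itc"`: injection indices `1:n_inj`).
#' @param noise Gaussian noise standard deviation (response units).
#' @param seed Integer seed.
#' @param meta Auxiliary constants (ITC geometry).
#' @return A [response_dataset()] with `sigma = noise`.
#' @export
generate_dataset <- function(model, params, x, noise = 0, seed = 1,
                             meta = list()) {
  model <- match.arg(model, MODEL_TAGS)
  f <- model_fun(model, meta)
  y0 <- f(x, as.list(params))
  y <- with_seed(seed, y0 + stats::rnorm(length(x), 0, noise))
  response_dataset(x, y, sigma = if (noise > 0) noise, model = model,
                   meta = meta)
}

half_point <- function(x, y, target) {
  out <- tryCatch(stats::approx(y, x, xout = target, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(out)) stats::median(x) else out
}

default_start <- function(data) {
  x <- data$x; y <- data$y
  switch(data$model,
    hill = list(i_max = max(y),
                k05 = max(min(x) + 1e-6, half_point(x, y, max(y) / 2),
                          na.rm = TRUE), h = 1),
    titration = list(i_min = min(y), i_max = max(y),
                     pk_app = stats::median(x), n = 1),
    mst = list(f_free = y[1], f_bound = y[length(y)],
               k_d = max(min(x), half_point(x, y, (y[1] + y[length(y)]) / 2),
                         na.rm = TRUE)),
    itc = list(n = 1, k_d = data$meta$cell_conc / 10, dh = y[1]))
}

# box constraints keeping the optimizer inside the models' domains
param_bounds <- function(model, start) {
  lower <- rep(-Inf, length(start))
  names(lower) <- names(start)
  pos <- switch(model, hill = c("k05", "h"), titration = "n",
                mst = "k_d", itc = c("n", "k_d"), character(0))
  lower[pos] <- 1e-9
  lower
}

#' Fit a response model by weighted nonlinear least squares
#'
#' Levenberg-Marquardt fit of the dataset's tagged model, weighted by
#' `1/sigma^2` when uncertainties are present. Non-convergence or a
#' singular fit is reported in the result, not raised.
#'
#' @param data A [response_dataset()].
#' @param start Optional named list of starting values; defaults are
#'   derived from the data.
#' @return Object of class `fit_result`: `params` (estimates), `se`
#'   (asymptotic standard errors), `residuals`, `fitted`, `converged`,
#'   `model`, and the underlying `nls` object as `fit`.
#' @export
fit_model <- function(data, start = NULL) {
  stopifnot(inherits(data, "response_dataset"))
  if (data$model == "transient")
    stop("transient traces are summarized with transient_summary(), not fitted")
  if (is.null(start)) start <- default_start(data)
  f <- model_fun(data$model, data$meta)
  if (length(data$x) < length(start) + 1)
    stop("need more points than parameters")
  w <- if (!is.null(data$sigma)) 1 / data$sigma^2
  rhs <- switch(data$model,
    hill = "i_max * x^h / (k05^h + x^h)",
    titration = "i_min + (i_max - i_min) / (1 + 10^(n * (pk_app - pH)))",
    mst = "f_free + (f_bound - f_free) * x / (k_d + x)",
    itc = "itc_injection_heats(n, k_d, dh, CC, CV, IV, SC, NI)[x]")
  if (data$model == "titration") rhs <- gsub("pH", "x", rhs)
  env <- new.env(parent = asNamespace("amtkit"))
  if (data$model == "itc") {
    env$CC <- data$meta$cell_conc; env$CV <- data$meta$cell_vol
    env$IV <- data$meta$inj_vol; env$SC <- data$meta$syringe_conc
    env$NI <- length(data$x)
  }
  form <- stats::as.formula(paste("y ~", rhs), env = env)
  dl <- list(y = data$y, x = data$x)
  args <- list(form, data = dl, start = start,
               lower = param_bounds(data$model, start),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(w)) {
    dl$.w <- w
    args$data <- dl
    args$weights <- quote(.w)
  }
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(params = unlist(start), se = rep(NA_real_,
             length(start)), residuals = rep(NA_real_, length(data$x)),
             fitted = rep(NA_real_, length(data$x)), converged = FALSE,
             message = conditionMessage(fit), model = data$model, fit = NULL),
             class = "fit_result"))
  }
  sm <- summary(fit)
  est <- stats::coef(fit)
  structure(list(params = est, se = sm$coefficients[, "Std. Error"],
                 residuals = stats::resid(fit), fitted = stats::fitted(fit),
                 converged = fit$convInfo$isConv, message = fit$convInfo$stopMessage,
                 model = data$model, fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): %s\n", x$model,
              if (x$converged) "converged" else paste("NOT converged:", x$message)))
  if (!is.null(x$fit)) {
    tab <- cbind(estimate = x$params, std.error = x$se)
    print(signif(tab, 5))
    cat(sprintf("residual sum of squares: %.4g\n", sum(x$residuals^2)))
  }
  invisible(x)
}

#' Read and write response datasets
#'
#' Delimited text with a `# model=` metadata line, optional further
#' `# key=value` lines (ITC geometry), a header `x y [sigma]` and one
#' point per row.
#'
#' @param path File path.
#' @return A [response_dataset()].
#' @export
read_response <- function(path) {
  lines <- readLines(path, warn = FALSE)
  metal <- grep("^\\s*#", lines, value = TRUE)
  kv <- regmatches(metal, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*([^ ]+)", metal))
  meta <- list()
  for (m in kv) if (length(m) == 3)
    meta[[m[2]]] <- if (grepl("^[-0-9.eE+]+$", m[3])) as.numeric(m[3]) else m[3]
  model <- meta$model
  if (is.null(model)) stop("missing '# model=' metadata line")
  meta$model <- NULL
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) stop("empty dataset: ", path)
  toks <- strsplit(trimws(body), "[,[:space:]]+")
  hdr <- tolower(toks[[1]])
  vals <- t(vapply(toks[-1], function(v) as.numeric(v[seq_along(hdr)]),
                   numeric(length(hdr))))
  response_dataset(vals[, 1], vals[, 2],
                   sigma = if ("sigma" %in% hdr) vals[, which(hdr == "sigma")],
                   model = model, meta = meta)
}

#' @rdname read_response
#' @param data A [response_dataset()].
#' @export
write_response <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# model=", data$model), con)
  for (nm in names(data$meta))
    writeLines(sprintf("# %s=%g", nm, data$meta[[nm]]), con)
  has_s <- !is.null(data$sigma)
  writeLines(paste(c("x", "y", if (has_s) "sigma"), collapse = " "), con)
  tab <- cbind(data$x, data$y, if (has_s) data$sigma)
  writeLines(apply(signif(tab, 9), 1, paste, collapse = " "), con)
  invisible(path)
}
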