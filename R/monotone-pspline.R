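#' Build a B-spline basis over the observed rate range
#'
#' Constructs `K` B-spline basis functions of the given degree on equally
#' spaced knots spanning the data range, with boundary knots repeated
#' `degree + 1` times. The basis is non-negative and sums to one at every
#' point of the support (partition of unity).
#'
#' @param x numeric vector of rates (mm/yr) whose range sets the support.
#' @param K number of basis functions; must be at least `degree + 1`.
#' @param degree spline degree, default 3 (cubic).
#' @return a `spline_basis`: list with `degree`, `K`, `knots` (full knot
#'   vector) and `support`.
#' @export
build_basis <- function(x, K = 12, degree = 3) {
  if (K < degree + 1) stop("K must be at least degree + 1 = ", degree + 1)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) stop("x must contain at least 2 distinct values")
  a <- min(x); b <- max(x)
  inner <- seq(a, b, length.out = K - degree + 1)
  knots <- c(rep(a, degree), inner, rep(b, degree))
  structure(list(degree = degree, K = K, knots = knots, support = c(a, b)),
            class = "spline_basis")
}

#' Evaluate a B-spline basis
#'
#' Returns the basis matrix at the given points. Points outside the support
#' are clamped to the nearest boundary, so the implied regression function is
#' held flat beyond the fitted range (needed because projected future rates
#' can exceed the Holocene range the model was fitted on).
#'
#' @param basis a [build_basis()] object.
#' @param x evaluation points, mm/yr.
#' @return numeric matrix, `length(x)` rows by `K` columns.
#' @export
eval_basis <- function(basis, x) {
  stopifnot(inherits(basis, "spline_basis"))
  xc <- pmin(pmax(x, basis$support[1]), basis$support[2])
  B <- splines::splineDesign(basis$knots, xc, ord = basis$degree + 1)
  dimnames(B) <- list(NULL, paste0("b", seq_len(basis$K)))
  B
}

#' Model configuration for the monotone P-spline tendency model
#'
#' @param K number of B-spline basis functions (default 12).
#' @param degree spline degree (default 3, cubic).
#' @param monotone enforce non-decreasing probability in rate (default TRUE).
#' @param alpha1_prior_sd prior SD of the first spline coefficient
#'   (Normal(0, sd^2); default 10, weakly informative on the logit scale).
#' @param sigma_scale scale of the half-Cauchy prior on the smoothing scale
#'   sigma of the coefficient increments (default 1).
#' @param chains number of MCMC chains (default 4, minimum 2).
#' @param iter iterations per chain including burn-in (default 20000).
#' @param burn burn-in iterations dropped per chain (default 10000).
#' @param thin thinning interval for retained draws (default 10).
#' @param seed RNG seed; recorded in the output.
#' @return a `model_config` list.
#' @export
model_config <- function(K = 12, degree = 3, monotone = TRUE,
                         alpha1_prior_sd = 10, sigma_scale = 1,
                         chains = 4, iter = 20000, burn = 10000, thin = 10,
                         seed = 1) {
  if (iter <= burn) stop("iter must exceed burn")
  if (chains < 2) stop("at least 2 chains are required for diagnostics")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(K = K, degree = degree, monotone = monotone,
                 alpha1_prior_sd = alpha1_prior_sd, sigma_scale = sigma_scale,
                 chains = chains, iter = iter, burn = burn, thin = thin,
                 seed = seed),
            class = "model_config")
}

#' Fit the Bayesian monotone penalized B-spline tendency model
#'
#' Models binary sea-level tendencies `y` (1 = positive tendency, marsh
#' retreat) as Bernoulli with logit probability expanded in a cubic B-spline
#' basis of the rate of relative sea-level rise. First-order differences of
#' adjacent spline coefficients get a Normal(0, sigma^2) shrinkage prior
#' (the P-spline penalty); when `monotone = TRUE` the differences are
#' constrained non-negative, so the fitted probability curve can only rise
#' with the rate. Sampling uses an adaptive random-walk
#' Metropolis-within-Gibbs over the first coefficient, the increments, and
#' the log smoothing scale.
#'
#' @param data a `tendency_dataset` from [encode_tendencies()], or any list
#'   with numeric `x` and 0/1 `y`.
#' @param config a [model_config()].
#' @return a `tendency_posterior`: retained draws of the coefficient vector
#'   alpha (columns `alpha_1..alpha_K`) and `sigma`, chain ids, the basis,
#'   split R-hat and effective-sample-size diagnostics, acceptance rates, and
#'   the configuration (seed included).
#' @export
fit_tendency_model <- function(data, config = model_config()) {
  x <- as.numeric(data$x); y <- as.integer(data$y)
  if (length(x) != length(y)) stop("x and y must be parallel")
  if (any(!is.finite(x))) stop("x contains non-finite values")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  n <- length(y)
  one_class <- length(unique(y)) < 2
  if (n < 20 || one_class)
    warning("fewer than 20 observations or a single response class: ",
            "the posterior will be prior-dominated", call. = FALSE)

  basis <- build_basis(x, K = config$K, degree = config$degree)
  B <- eval_basis(basis, x)
  # eta = alpha_1 + Cd %*% delta with Cd[, j] = rowSums(B[, (j+1):K])
  Cd <- t(apply(B, 1, function(r) rev(cumsum(rev(r)))))[, -1, drop = FALSE]

  p0 <- min(max(mean(y), 1 / (n + 2)), 1 - 1 / (n + 2))
  nd <- config$K - 1
  draws_list <- vector("list", config$chains)
  accept <- matrix(NA_real_, config$chains, nd + 2)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + 1000L * (ch - 1L))
    init <- c(qlogis(p0) + rnorm(1, 0, 0.3),
              if (config$monotone) runif(nd, 0.005, 0.05)
              else rnorm(nd, 0, 0.05),
              rnorm(1, 0, 0.3))
    res <- mcmc_pspline_chain(Cd, y, config$iter, config$burn, config$thin,
                              config$monotone, config$alpha1_prior_sd,
                              config$sigma_scale, init)
    draws_list[[ch]] <- res$draws
    accept[ch, ] <- res$accept_rate
  }
  n_keep <- nrow(draws_list[[1]])
  raw <- do.call(rbind, draws_list)
  # map (alpha_1, delta_2..delta_K) to the coefficient vector alpha
  alpha <- t(apply(raw[, seq_len(config$K), drop = FALSE], 1, cumsum))
  draws <- cbind(alpha, raw[, config$K + 1])
  colnames(draws) <- c(paste0("alpha_", seq_len(config$K)), "sigma")
  chain <- rep(seq_len(config$chains), each = n_keep)

  diag <- mcmc_diagnostics(draws, chain)
  if (any(diag$rhat > 1.05, na.rm = TRUE))
    warning("convergence not reached: max split R-hat = ",
            sprintf("%.3f", max(diag$rhat, na.rm = TRUE)), call. = FALSE)

  structure(list(draws = draws, chain = chain, basis = basis,
                 diagnostics = diag, accept_rate = accept, config = config,
                 degenerate = one_class, n = n),
            class = "tendency_posterior")
}

#' @export
print.tendency_posterior <- function(x, ...) {
  cat(sprintf("tendency_posterior: %d draws (%d chains), K = %d %s\n",
              nrow(x$draws), x$config$chains, x$config$K,
              if (x$config$monotone) "(monotone)" else "(unconstrained)"))
  cat(sprintf("  fitted to n = %d; support %.2f to %.2f mm/yr\n",
              x$n, x$basis$support[1], x$basis$support[2]))
  cat(sprintf("  max split R-hat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  if (isTRUE(x$degenerate))
    cat("  NOTE: single-class response; posterior is boundary-degenerate\n")
  invisible(x)
}

# Split R-hat and a Geyer initial-positive-sequence ESS, per parameter.
mcmc_diagnostics <- function(draws, chain) {
  split_chains <- function(v, ch) {
    out <- list()
    for (c0 in unique(ch)) {
      z <- v[ch == c0]
      h <- floor(length(z) / 2)
      out <- c(out, list(z[seq_len(h)], z[h + seq_len(h)]))
    }
    out
  }
  rhat_one <- function(v, ch) {
    parts <- split_chains(v, ch)
    m <- length(parts); nn <- length(parts[[1]])
    if (nn < 2) return(NA_real_)
    means <- vapply(parts, mean, 0); vars <- vapply(parts, var, 0)
    W <- mean(vars); Bv <- nn * var(means)
    if (W == 0) return(1)
    sqrt(((nn - 1) / nn * W + Bv / nn) / W)
  }
  ess_one <- function(v, ch) {
    total <- 0
    for (c0 in unique(ch)) {
      z <- v[ch == c0]; nz <- length(z)
      if (var(z) == 0) { total <- total + nz; next }
      ac <- stats::acf(z, lag.max = min(nz - 1, 200), plot = FALSE)$acf[-1]
      s <- 0; k <- 1
      while (k + 1 <= length(ac)) {
        pr <- ac[k] + ac[k + 1]
        if (pr < 0) break
        s <- s + pr; k <- k + 2
      }
      total <- total + nz / (1 + 2 * s)
    }
    total
  }
  data.frame(parameter = colnames(draws),
             rhat = apply(draws, 2, rhat_one, ch = chain),
             ess = apply(draws, 2, ess_one, ch = chain),
             row.names = NULL)
}

#' Posterior probability curve with credible band
#'
#' Evaluates the posterior of the retreat probability p(rate) on a grid:
#' posterior mean and equal-tailed 95% credible band (2.5 and 97.5
#' percentiles over draws). Outside the fitted support the curve is held
#' flat at its boundary value.
#'
#' @param post a [fit_tendency_model()] posterior.
#' @param grid rate grid, mm/yr (default 401 points over the support).
#' @return a `probability_curve` data frame with columns `grid`, `mean`,
#'   `lo`, `hi`.
#' @export
probability_curve <- function(post, grid = NULL) {
  stopifnot(inherits(post, "tendency_posterior"))
  if (nrow(post$draws) == 0) stop("posterior contains no draws")
  if (is.null(grid))
    grid <- seq(post$basis$support[1], post$basis$support[2], length.out = 401)
  A <- eval_basis(post$basis, grid)
  alpha <- post$draws[, seq_len(post$basis$K), drop = FALSE]
  p <- plogis(A %*% t(alpha))               # grid x draws
  qs <- apply(p, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(grid = grid, mean = rowMeans(p),
                    lo = qs[1, ], hi = qs[2, ])
  structure(out, support = post$basis$support,
            monotone = post$config$monotone,
            class = c("probability_curve", "data.frame"))
}

#' Look up retreat probabilities on a fitted curve
#'
#' Linear interpolation of the posterior-mean curve between grid points, held
#' flat beyond the fitted support.
#'
#' @param curve a [probability_curve()].
#' @param rates rates to evaluate, mm/yr.
#' @return probabilities in (0, 1).
#' @export
curve_lookup <- function(curve, rates) {
  stopifnot(inherits(curve, "probability_curve"))
  approx(curve$grid, curve$mean, xout = rates, method = "linear",
         rule = 2)$y
}

#' Rate at which the retreat probability reaches a target
#'
#' The smallest rate on the curve grid whose posterior-mean probability is at
#' least `p_target`, refined by linear interpolation between the bracketing
#' grid points. If the curve never reaches the target the result is `NA` with
#' a `status` attribute saying in which direction it was missed.
#'
#' @param curve a [probability_curve()].
#' @param p_target target probability in (0, 1).
#' @return rate in mm/yr (or `NA` with `attr(., "status")`).
#' @export
rate_at_probability <- function(curve, p_target) {
  stopifnot(inherits(curve, "probability_curve"),
            p_target > 0, p_target < 1)
  m <- curve$mean
  if (p_target > max(m))
    return(structure(NA_real_, status = "not reached: above curve maximum"))
  idx <- which(m >= p_target)[1]
  if (idx == 1)
    return(structure(curve$grid[1], status = "at or below curve minimum"))
  x0 <- curve$grid[idx - 1]; x1 <- curve$grid[idx]
  y0 <- m[idx - 1]; y1 <- m[idx]
  structure(x0 + (p_target - y0) / (y1 - y0) * (x1 - x0), status = "ok")
}

#' Write a posterior artifact to JSON
#'
#' Serializes configuration, knot vector, the flattened draw matrix and
#' diagnostics; schema versioned so artifacts remain readable.
#'
#' @param post a `tendency_posterior`.
#' @param path output path.
#' @export
write_posterior <- function(post, path) {
  obj <- list(schema = "marshretreat/posterior/1",
              config = unclass(post$config),
              basis = unclass(post$basis),
              parameters = colnames(post$draws),
              draws = as.vector(post$draws),
              n_draws = nrow(post$draws),
              chain = post$chain,
              diagnostics = post$diagnostics,
              n = post$n, degenerate = post$degenerate)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a posterior artifact written by [write_posterior()]
#'
#' @param path path to the JSON artifact.
#' @return a `tendency_posterior`.
#' @export
read_posterior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "marshretreat/posterior/1"))
    stop("unrecognized posterior schema: ", obj$schema)
  draws <- matrix(obj$draws, nrow = obj$n_draws)
  colnames(draws) <- obj$parameters
  basis <- structure(obj$basis, class = "spline_basis")
  config <- structure(obj$config, class = "model_config")
  structure(list(draws = draws, chain = obj$chain, basis = basis,
                 diagnostics = obj$diagnostics, accept_rate = NULL,
                 config = config, degenerate = obj$degenerate, n = obj$n),
            class = "tendency_posterior")
}

#' Write a probability curve as delimited text
#'
#' Columns `grid,mean,lo,hi`.
#'
#' @param curve a [probability_curve()].
#' @param path output path.
#' @export
write_probability_curve <- function(curve, path) {
  write.csv(as.data.frame(curve)[, c("grid", "mean", "lo", "hi")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
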