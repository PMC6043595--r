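# Independent oracles and fixture builders shared across the suite.

# Cox-de Boor recursion, coded independently of splines::splineDesign.
# Valid for x strictly inside the knot span (half-open interval convention).
deboor_one <- function(k, d, x, knots) {
  if (d == 0) return(as.numeric(knots[k] <= x & x < knots[k + 1]))
  t1 <- knots[k + d] - knots[k]
  a <- if (t1 > 0) (x - knots[k]) / t1 * deboor_one(k, d - 1, x, knots) else 0
  t2 <- knots[k + d + 1] - knots[k + 1]
  b <- if (t2 > 0) (knots[k + d + 1] - x) / t2 *
    deboor_one(k + 1, d - 1, x, knots) else 0
  a + b
}

deboor_row <- function(knots, x, degree) {
  nb <- length(knots) - degree - 1
  vapply(seq_len(nb), deboor_one, numeric(length(x)),
         d = degree, x = x, knots = knots)
}

# Brute-force prefix maximum.
prefix_max <- function(v) vapply(seq_along(v), function(i) max(v[seq_len(i)]), 0)

# Brute-force per-bin, per-class recount for tendency_proportions.
recount_bins <- function(rates, tendency, width) {
  left <- floor(rates / width) * width
  do.call(rbind, lapply(sort(unique(left)), function(e) {
    in_bin <- left == e
    data.frame(bin_left_edge = e,
               n_positive = sum(in_bin & tendency == "positive"),
               n_negative = sum(in_bin & tendency == "negative"),
               n_none = sum(in_bin & tendency == "none"))
  }))
}

# A small well-formed index-point file on disk; returns its path.
write_ip_fixture <- function(rows = NULL) {
  if (is.null(rows)) rows <- data.frame(
    point_id = paste0("P", 1:5), region_id = "R1",
    lat = 51 + (1:5) / 10, lon = -3 + (1:5) / 10,
    age_cal_bp = c(1500, 3200, 4800, 7000, 9500),
    tendency = c("positive", "negative", "none", "positive", "negative"),
    contact = c("gradual", "gradual", "erosional", "gradual", "erosional"))
  path <- tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# In-memory index_point_db without touching disk.
make_db <- function(tendency, contact = rep("gradual", length(tendency)),
                    age = rep(5000, length(tendency))) {
  n <- length(tendency)
  pts <- data.frame(point_id = paste0("P", seq_len(n)), region_id = "R1",
                    lat = 51, lon = -3, age = age,
                    tendency = tendency, contact = contact,
                    stringsAsFactors = FALSE)
  db <- read_index_points(write_ip_fixture(data.frame(
    point_id = pts$point_id, region_id = pts$region_id, lat = pts$lat,
    lon = pts$lon, age_cal_bp = pts$age, tendency = pts$tendency,
    contact = pts$contact)))
  db
}

# Uniform-rate synthetic tendency dataset drawn from a known truth curve.
make_sim_dataset <- function(n, truth = truth_curve(), seed = 1,
                             xlim = c(-5.5, 10)) {
  set.seed(seed)
  x <- runif(n, xlim[1], xlim[2])
  y <- rbinom(n, 1, truth$p(x))
  list(x = x, y = y, point_ids = paste0("S", seq_len(n)), n = n)
}

# Fast MCMC settings for unit tests (acceptance uses larger runs).
quick_config <- function(seed = 1, ...) {
  model_config(chains = 2, iter = 3000, burn = 1500, thin = 3,
               seed = seed, ...)
}

# Hand-built probability_curve for coupling tests.
make_curve <- function(grid, mean, lo = mean, hi = mean, monotone = TRUE) {
  structure(data.frame(grid = grid, mean = mean, lo = lo, hi = hi),
            support = range(grid), monotone = monotone,
            class = c("probability_curve", "data.frame"))
}
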