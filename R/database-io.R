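#' @useDynLib marshretreat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx quantile rbinom runif rnorm var plogis qlogis
#' @importFrom utils read.csv write.csv head
NULL

TENDENCY_LEVELS <- c("positive", "negative", "none")
CONTACT_LEVELS <- c("gradual", "erosional")
AGE_RANGE <- c(0, 12000)

#' Canonical index-point file dialect
#'
#' Describes how a delimited index-point file maps onto the canonical schema:
#' which column holds each field and how its tendency/contact labels map onto
#' the canonical levels. The canonical header is
#' `point_id,region_id,lat,lon,age_cal_bp,tendency,contact` with tendency in
#' `positive`/`negative`/`none` and contact in `gradual`/`erosional`.
#'
#' @param columns named character vector mapping canonical field names to the
#'   column names used in the file.
#' @param tendency_map named character vector mapping file labels to canonical
#'   tendency levels, e.g. `c(POS = "positive")`. Canonical labels always pass.
#' @param contact_map named character vector mapping file labels to canonical
#'   contact levels.
#' @param sep field separator, default comma.
#' @return a list of class `ip_dialect`.
#' @export
ip_dialect <- function(columns = c(point_id = "point_id", region_id = "region_id",
                                   lat = "lat", lon = "lon", age_cal_bp = "age_cal_bp",
                                   tendency = "tendency", contact = "contact"),
                       tendency_map = character(), contact_map = character(),
                       sep = ",") {
  required <- c("point_id", "region_id", "lat", "lon", "age_cal_bp",
                "tendency", "contact")
  missing <- setdiff(required, names(columns))
  if (length(missing) > 0)
    stop("dialect is missing column mappings for: ", paste(missing, collapse = ", "))
  structure(list(columns = columns, tendency_map = tendency_map,
                 contact_map = contact_map, sep = sep),
            class = "ip_dialect")
}

new_index_point_db <- function(points, source = NA_character_,
                               filters = NULL, errors = NULL) {
  if (is.null(filters))
    filters <- data.frame(point_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  if (is.null(errors))
    errors <- data.frame(line = integer(), message = character(),
                         stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(points$point_id))
  structure(list(points = points,
                 provenance = list(source = source, filters = filters)),
            errors = errors, class = "index_point_db")
}

#' Read a sea-level index-point database
#'
#' Parses a delimited file of dated stratigraphic contacts into an
#' `index_point_db`. Every row either becomes an index point or is reported,
#' with its line number, in the attached error table; rows are never dropped
#' silently. A row is rejected when its age is unparseable or outside
#' 0--12,000 cal yr BP, its coordinates are unparseable, or its tendency or
#' contact label is not covered by the dialect.
#'
#' @param path path to the delimited file.
#' @param dialect an [ip_dialect()] describing column names and label maps.
#' @return an `index_point_db`: a list with `points` (data frame) and
#'   `provenance`; parse errors are in `attr(db, "errors")`.
#' @export
read_index_points <- function(path, dialect = ip_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    stop("empty index-point file: ", path, call. = FALSE)
  raw <- read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  cols <- dialect$columns
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing) > 0)
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(raw) == 0)
    stop("empty index-point file (header only): ", path, call. = FALSE)

  get <- function(field) raw[[cols[[field]]]]
  map_labels <- function(x, map, levels) {
    out <- ifelse(x %in% names(map), unname(map[x]), x)
    ifelse(out %in% levels, out, NA_character_)
  }
  n <- nrow(raw)
  age <- suppressWarnings(as.numeric(get("age_cal_bp")))
  lat <- suppressWarnings(as.numeric(get("lat")))
  lon <- suppressWarnings(as.numeric(get("lon")))
  tendency <- map_labels(get("tendency"), dialect$tendency_map, TENDENCY_LEVELS)
  contact <- map_labels(get("contact"), dialect$contact_map, CONTACT_LEVELS)

  msgs <- vector("list", n)
  add_err <- function(idx, msg) for (i in which(idx)) msgs[[i]] <<- c(msgs[[i]], msg)
  add_err(is.na(age), "unparseable age")
  add_err(!is.na(age) & (age < AGE_RANGE[1] | age > AGE_RANGE[2]),
          sprintf("age outside [%d, %d] cal yr BP", AGE_RANGE[1], AGE_RANGE[2]))
  add_err(is.na(lat) | is.na(lon), "unparseable coordinates")
  add_err(is.na(tendency), "unknown tendency label")
  add_err(is.na(contact), "unknown contact label")

  has_err <- vapply(msgs, function(m) length(m) > 0, logical(1))
  # +1 header line: error lines refer to file line numbers
  errors <- data.frame(
    line = which(has_err) + 1L,
    message = vapply(msgs[has_err], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE)

  keep <- !has_err
  points <- data.frame(
    point_id = get("point_id")[keep],
    region_id = get("region_id")[keep],
    lat = lat[keep], lon = lon[keep],
    age = age[keep],
    tendency = tendency[keep],
    contact = contact[keep],
    stringsAsFactors = FALSE)
  if (anyDuplicated(points$point_id))
    stop("duplicate point_id values: ",
         paste(unique(points$point_id[duplicated(points$point_id)]), collapse = ", "))
  new_index_point_db(points, source = path, errors = errors)
}

#' @export
print.index_point_db <- function(x, ...) {
  cat("index_point_db:", nrow(x$points), "points")
  if (!is.na(x$provenance$source)) cat(" from", x$provenance$source)
  cat("\n")
  tab <- table(factor(x$points$tendency, TENDENCY_LEVELS))
  cat("  tendencies:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  nf <- nrow(x$provenance$filters)
  if (nf > 0) cat("  filtered out:", nf, "points (see provenance$filters)\n")
  ne <- nrow(attr(x, "errors") %||% data.frame())
  if (ne > 0) cat("  parse errors:", ne, "rows rejected\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep only index points from gradual contacts
#'
#' Erosional contacts date only the erosion event, not the change in marine
#' influence, so they are excluded before modelling. Every exclusion is logged
#' in the provenance filter history with reason `"erosional"`. Idempotent.
#'
#' @param db an `index_point_db`.
#' @return an `index_point_db` containing exactly the gradual-contact points.
#' @export
filter_gradual <- function(db) {
  stopifnot(inherits(db, "index_point_db"))
  drop <- db$points$contact != "gradual"
  new_filters <- rbind(
    db$provenance$filters,
    data.frame(point_id = db$points$point_id[drop],
               reason = rep("erosional", sum(drop)),
               stringsAsFactors = FALSE))
  out <- new_index_point_db(db$points[!drop, , drop = FALSE],
                            source = db$provenance$source,
                            filters = new_filters,
                            errors = attr(db, "errors"))
  rownames(out$points) <- NULL
  out
}

#' Write the exclusion log
#'
#' One line per excluded point, tab-separated `point_id<TAB>reason`.
#'
#' @param db an `index_point_db`.
#' @param path output path.
#' @export
write_filter_log <- function(db, path) {
  f <- db$provenance$filters
  writeLines(paste(f$point_id, f$reason, sep = "\t"), path)
  invisible(path)
}

#' Encode tendencies as a binary modelling dataset
#'
#' Pairs each index point's assigned rate of relative sea-level rise with a
#' binary response: positive tendency (marsh retreat) = 1; negative tendency
#' (marsh expansion) = 0. No-tendency points (marsh keeping pace) are coded 0
#' by default; set `none_as_zero = FALSE` to drop them instead.
#'
#' @param db an `index_point_db`.
#' @param rates numeric vector of rates (mm/yr), parallel to `db$points`.
#' @param none_as_zero if `TRUE` (default) no-tendency points are coded 0;
#'   if `FALSE` they are excluded from the dataset.
#' @return a `tendency_dataset`: list with `x` (rates, mm/yr), `y` (0/1),
#'   `point_ids`, `n`.
#' @export
encode_tendencies <- function(db, rates, none_as_zero = TRUE) {
  stopifnot(inherits(db, "index_point_db"))
  if (length(rates) != nrow(db$points))
    stop("rates (", length(rates), ") not parallel to db points (",
         nrow(db$points), ")")
  if (any(!is.finite(rates)) && nrow(db$points) > 0)
    stop("rates contain non-finite values")
  keep <- rep(TRUE, nrow(db$points))
  if (!none_as_zero) keep <- db$points$tendency != "none"
  tend <- db$points$tendency[keep]
  structure(list(x = as.numeric(rates[keep]),
                 y = as.integer(tend == "positive"),
                 point_ids = db$points$point_id[keep],
                 n = sum(keep)),
            class = "tendency_dataset")
}

#' @export
print.tendency_dataset <- function(x, ...) {
  cat("tendency_dataset: n =", x$n, "|", sum(x$y), "positive,",
      x$n - sum(x$y), "non-positive\n")
  if (x$n > 0)
    cat(sprintf("  rates: %.2f to %.2f mm/yr\n", min(x$x), max(x$x)))
  invisible(x)
}

#' Binned tendency proportions by rate of sea-level rise
#'
#' Counts and within-bin proportions of positive, negative and no-tendency
#' index points in half-open rate bins `[a, a + width)` anchored at integer
#' multiples of the bin width (default 0.5 mm/yr).
#'
#' @param db an `index_point_db`.
#' @param rates numeric vector of rates (mm/yr), parallel to `db$points`.
#' @param bin_width bin width in mm/yr, default 0.5.
#' @return data frame with `bin_left_edge`, per-class counts
#'   (`n_positive`, `n_negative`, `n_none`), `n_total` and per-class
#'   proportions; one row per non-empty bin.
#' @export
tendency_proportions <- function(db, rates, bin_width = 0.5) {
  stopifnot(inherits(db, "index_point_db"), bin_width > 0)
  if (length(rates) != nrow(db$points)) stop("rates not parallel to db points")
  if (nrow(db$points) == 0)
    return(data.frame(bin_left_edge = numeric(), n_positive = integer(),
                      n_negative = integer(), n_none = integer(),
                      n_total = integer(), p_positive = numeric(),
                      p_negative = numeric(), p_none = numeric()))
  left <- floor(rates / bin_width) * bin_width
  tend <- factor(db$points$tendency, TENDENCY_LEVELS)
  tab <- table(left = left, tendency = tend)
  edges <- as.numeric(rownames(tab))
  out <- data.frame(
    bin_left_edge = edges,
    n_positive = as.integer(tab[, "positive"]),
    n_negative = as.integer(tab[, "negative"]),
    n_none = as.integer(tab[, "none"]))
  out$n_total <- out$n_positive + out$n_negative + out$n_none
  out$p_positive <- out$n_positive / out$n_total
  out$p_negative <- out$n_negative / out$n_total
  out$p_none <- out$n_none / out$n_total
  out[order(out$bin_left_edge), , drop = FALSE]
}

#' Write an index-point database in the canonical file format
#'
#' @param db an `index_point_db`.
#' @param path output path.
#' @export
write_index_points <- function(db, path) {
  pts <- db$points
  out <- data.frame(point_id = pts$point_id, region_id = pts$region_id,
                    lat = pts$lat, lon = pts$lon, age_cal_bp = pts$age,
                    tendency = pts$tendency, contact = pts$contact)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
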