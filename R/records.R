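RECORD_COLUMNS <- c("tag_id", "species", "site", "date", "length_mm",
                    "buoyant_weight_mg", "smr_mgO2_per_h_per_g",
                    "heart_rate_bpm")

#' Read field capture records from CSV
#'
#' Expected header:
#' `tag_id,species,site,date,length_mm,buoyant_weight_mg,smr_mgO2_per_h_per_g,heart_rate_bpm`.
#' Dates are ISO-8601 (`YYYY-MM-DD`); empty strings are missing values.
#' Species tokens are `chiton_granosus` / `scurria_zebrina`, site tokens
#' `talcaruca` / `quintay`.
#'
#' @param path CSV file path.
#' @return Data frame of capture records (one row per observation event).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(tag_id = "character"))
  missing_cols <- setdiff(RECORD_COLUMNS, names(d))
  if (length(missing_cols))
    stop("records file missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  validate_records(d)
}

#' Validate a capture-record table
#'
#' Checks tag ids, species/site tokens, ISO dates and positivity of optional
#' measurements; reports the offending row number on failure.
#'
#' @param d Data frame with the capture-record columns.
#' @return The validated data frame with `date` parsed to `Date`.
#' @export
validate_records <- function(d) {
  bad_tag <- which(is.na(d$tag_id) | !nzchar(trimws(d$tag_id)))
  if (length(bad_tag))
    stop("empty tag_id at row ", bad_tag[1], call. = FALSE)
  bad_sp <- which(!(d$species %in% SPECIES))
  if (length(bad_sp))
    stop(sprintf("unknown species '%s' at row %d", d$species[bad_sp[1]],
                 bad_sp[1]), call. = FALSE)
  bad_site <- which(!(d$site %in% SITES))
  if (length(bad_site))
    stop(sprintf("unknown site '%s' at row %d", d$site[bad_site[1]],
                 bad_site[1]), call. = FALSE)
  dates <- as.Date(as.character(d$date), format = "%Y-%m-%d")
  bad_date <- which(is.na(dates))
  if (length(bad_date))
    stop(sprintf("unparseable date '%s' at row %d", d$date[bad_date[1]],
                 bad_date[1]), call. = FALSE)
  d$date <- dates
  for (col in c("length_mm", "buoyant_weight_mg", "smr_mgO2_per_h_per_g",
                "heart_rate_bpm")) {
    if (!col %in% names(d)) next
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop(sprintf("non-positive %s at row %d", col, bad[1]), call. = FALSE)
    d[[col]] <- v
  }
  d
}

#' Build encounter histories for one site/species population
#'
#' Collapses capture records into an individuals-by-occasions binary
#' detection matrix. Each tagged individual becomes one row; any record in
#' month `t` sets `y[i, t] = 1` (multiple records within a month collapse to
#' a single detection); `first[i]` is the earliest detection. Per-individual
#' covariates (body length, standard metabolic rate) are taken from the
#' record at first capture and treated as time-constant.
#'
#' @param records Capture-record data frame (see [read_records()]).
#' @param calendar An `occasion_calendar` with effort attached.
#' @param site,species Population selectors; all records must match.
#' @return An object of class `encounter_histories`: list with `y` (n x T
#'   0/1 matrix), `first` (1-based first-capture occasions), `tag_ids`,
#'   `site`, `species`, `covariates` (data frame with `length_mm`, `smr`),
#'   and `searched` (logical length T).
#' @export
build_histories <- function(records, calendar, site, species) {
  site <- match_site(site); species <- match_species(species)
  key <- cell_key(site, species)
  searched <- calendar$searched[[key]]
  if (is.null(searched))
    stop("calendar has no effort attached for ", key, call. = FALSE)
  if (!all(records$site == site) || !all(records$species == species))
    stop("records contain rows not belonging to ", key, call. = FALSE)
  occ <- occasion_of(calendar, records$date)
  if (anyNA(occ))
    stop("record dated outside the calendar window (row ",
         which(is.na(occ))[1], ")", call. = FALSE)
  bad <- which(!searched[occ])
  if (length(bad))
    stop(sprintf(
      "detection in unsearched month: tag '%s' on %s (row %d); calendar/effort mismatch",
      records$tag_id[bad[1]], records$date[bad[1]], bad[1]), call. = FALSE)

  T <- calendar$n_occasions
  tags <- unique(records$tag_id)
  y <- matrix(0L, length(tags), T, dimnames = list(tags, NULL))
  y[cbind(match(records$tag_id, tags), occ)] <- 1L
  first <- apply(y, 1L, function(r) which(r == 1L)[1])

  first_rows <- records[order(occ, records$date), ]
  first_rows <- first_rows[!duplicated(first_rows$tag_id), ]
  first_rows <- first_rows[match(tags, first_rows$tag_id), ]
  covariates <- data.frame(
    length_mm = if ("length_mm" %in% names(records))
      first_rows$length_mm else rep(NA_real_, length(tags)),
    smr = if ("smr_mgO2_per_h_per_g" %in% names(records))
      first_rows$smr_mgO2_per_h_per_g else rep(NA_real_, length(tags)),
    row.names = NULL)

  new_histories(y, first, tags, site, species, covariates, searched)
}

new_histories <- function(y, first, tag_ids, site, species, covariates,
                          searched) {
  h <- structure(
    list(y = y, first = as.integer(first), tag_ids = tag_ids, site = site,
         species = species, covariates = covariates,
         searched = as.logical(searched)),
    class = "encounter_histories")
  validate_histories(h)
}

validate_histories <- function(h) {
  y <- h$y; T <- ncol(y); n <- nrow(y)
  if (n < 1L || T < 2L) stop("need n >= 1 individuals and T >= 2 occasions",
                             call. = FALSE)
  if (length(h$searched) != T)
    stop("searched mask length differs from number of occasions",
         call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary", call. = FALSE)
  if (any(y[cbind(seq_len(n), h$first)] != 1L))
    stop("y[i, first[i]] must be 1", call. = FALSE)
  for (i in seq_len(n))
    if (h$first[i] > 1L && any(y[i, seq_len(h$first[i] - 1L)] != 0L))
      stop("detection before first capture for individual ", i, call. = FALSE)
  if (any(y[, !h$searched, drop = FALSE] != 0L))
    stop("detection in an unsearched month", call. = FALSE)
  h
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat(sprintf(
    "Encounter histories: %d individuals x %d occasions (%s, %s), %d searched months\n",
    nrow(x$y), ncol(x$y), x$site, x$species, sum(x$searched)))
  invisible(x)
}

#' Restrict encounter histories to a contiguous occasion window
#'
#' Keeps only the occasions `start_occasion .. start_occasion + width - 1`,
#' drops individuals whose first capture falls outside the window, and
#' re-indexes first-capture occasions. Used for covariate survival models,
#' which are fit on a short window because the covariates are measured at
#' first capture and drift over time.
#'
#' @param histories An `encounter_histories` object.
#' @param start_occasion 1-based index of the first retained occasion.
#' @param width Number of occasions retained (default 6).
#' @return An `encounter_histories` object on the restricted window.
#' @export
restrict_window <- function(histories, start_occasion, width = 6L) {
  T <- ncol(histories$y)
  if (start_occasion < 1L || start_occasion + width - 1L > T)
    stop("window [", start_occasion, ", ", start_occasion + width - 1L,
         "] exceeds calendar with ", T, " occasions", call. = FALSE)
  cols <- start_occasion:(start_occasion + width - 1L)
  keep <- histories$first >= cols[1] & histories$first <= cols[length(cols)]
  if (!any(keep)) stop("no individual first-captured inside the window",
                       call. = FALSE)
  y <- histories$y[keep, cols, drop = FALSE]
  new_histories(y,
                histories$first[keep] - start_occasion + 1L,
                histories$tag_ids[keep], histories$site, histories$species,
                histories$covariates[keep, , drop = FALSE],
                histories$searched[cols])
}

#' Reduce encounter histories to an m-array
#'
#' The m-array is the standard sufficient statistic for time-structured CJS
#' likelihoods: for every release occasion `i` (a detection at `i < T`,
#' including re-releases after recapture) it counts first recaptures at each
#' later occasion `j`, and the animals never seen again.
#'
#' @param histories An `encounter_histories` object.
#' @return List of class `m_array` with `released` (length T-1),
#'   `recaptured` ((T-1) x T upper-triangular count matrix, column `j` =
#'   first recapture at occasion `j`), and `never_seen` (length T-1).
#' @export
m_array <- function(histories) {
  y <- histories$y; T <- ncol(y)
  released <- integer(T - 1L)
  recaptured <- matrix(0L, T - 1L, T)
  never_seen <- integer(T - 1L)
  for (i in seq_len(nrow(y))) {
    det <- which(y[i, ] == 1L)
    rel <- det[det < T]
    for (r in seq_along(rel)) {
      released[rel[r]] <- released[rel[r]] + 1L
      nxt <- det[det > rel[r]]
      if (length(nxt)) {
        recaptured[rel[r], nxt[1]] <- recaptured[rel[r], nxt[1]] + 1L
      } else {
        never_seen[rel[r]] <- never_seen[rel[r]] + 1L
      }
    }
  }
  structure(list(released = released, recaptured = recaptured,
                 never_seen = never_seen, n_occasions = T),
            class = "m_array")
}

validate_marray <- function(m) {
  T <- m$n_occasions
  for (i in seq_len(T - 1L))
    if (any(m$recaptured[i, seq_len(i)] != 0))
      stop("m-array has recaptures at or before release", call. = FALSE)
  if (!all(m$released == rowSums(m$recaptured) + m$never_seen))
    stop("m-array row sums do not balance", call. = FALSE)
  m
}

#' Write encounter histories to CSV or MARK-style .inp
#'
#' `write_histories` writes one row per individual with columns `tag_id`,
#' `first`, then `h1..hT` of 0/1. `write_inp` writes the classic
#' capture-history string format `/* tag */ 101001 1;`.
#'
#' @param histories An `encounter_histories` object.
#' @param path Output file path.
#' @export
write_histories <- function(histories, path) {
  T <- ncol(histories$y)
  d <- data.frame(tag_id = histories$tag_ids, first = histories$first)
  h <- as.data.frame(histories$y)
  names(h) <- paste0("h", seq_len(T))
  utils::write.csv(cbind(d, h), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histories
#' @export
write_inp <- function(histories, path) {
  lines <- sprintf("/* %s */ %s 1;", histories$tag_ids,
                   apply(histories$y, 1L, paste, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
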