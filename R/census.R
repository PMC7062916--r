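#' Effective diameter of a multi-stemmed individual
#'
#' Combines the stem diameters of one individual into a single effective DBH
#' as the square root of the sum of squared stem diameters, so that the
#' individual's basal area equals the summed basal area of its stems.
#'
#' @param dbh_cm numeric vector of stem diameters at breast height (cm), all
#'   positive. A single value is returned unchanged.
#' @return Effective DBH in cm.
#' @examples
#' combined_dbh(c(3, 4))   # 5
#' combined_dbh(10)        # 10
#' @export
combined_dbh <- function(dbh_cm) {
  if (length(dbh_cm) == 0L) {
    stop("combined_dbh(): need at least one stem diameter", call. = FALSE)
  }
  if (anyNA(dbh_cm) || any(dbh_cm <= 0)) {
    stop("combined_dbh(): stem diameters must be positive and non-missing",
         call. = FALSE)
  }
  sqrt(sum(dbh_cm^2))
}

#' Height of a multi-stemmed individual
#'
#' The individual's height is the height of its tallest stem.
#'
#' @param height_m numeric vector of stem heights (m). `NA` stems are ignored
#'   unless all are `NA`, in which case `NA` is returned (lianas may lack
#'   heights).
#' @return Height in m, or `NA` if no stem has a height.
#' @export
individual_height <- function(height_m) {
  if (length(height_m) == 0L) {
    stop("individual_height(): need at least one stem height", call. = FALSE)
  }
  h <- height_m[!is.na(height_m)]
  if (length(h) == 0L) return(NA_real_)
  if (any(h <= 0)) {
    stop("individual_height(): stem heights must be positive", call. = FALSE)
  }
  max(h)
}

.growth_forms <- c("tree", "palm", "liana", "tree_fern")

.census_columns <- c("plot_id", "individual_id", "stem_id", "dbh_cm",
                     "height_m", "growth_form", "species", "family")

#' Read and validate a stem census table
#'
#' Reads a long-format census file (one stem per row), validates it against
#' the census schema, and assembles one analysis record per individual:
#' multi-stem individuals get the root-sum-of-squares effective DBH and the
#' height of their tallest stem. The census inclusion threshold is a DBH of
#' 2.5 cm measured at 130 cm; smaller stems are a validation error by default.
#'
#' @param path path to a CSV file with columns `plot_id`, `individual_id`,
#'   `stem_id`, `dbh_cm`, `height_m`, `growth_form` (tree/palm/liana/
#'   tree_fern), `species`, `family`. Lines starting with `#` are ignored.
#'   Unresolved taxa are the empty string or `NA`.
#' @param min_dbh_cm census inclusion threshold in cm (default 2.5).
#' @param on_small_dbh `"error"` (default) or `"drop"`: what to do with rows
#'   below the threshold. Dropping warns with the offending row numbers.
#' @return A list with elements `stems` (validated stem table, one row per
#'   stem) and `individuals` (one row per individual with effective `dbh_cm`,
#'   `height_m`, `growth_form`, `species`, `family`, `n_stems`).
#' @export
read_census <- function(path, min_dbh_cm = 2.5,
                        on_small_dbh = c("error", "drop")) {
  on_small_dbh <- match.arg(on_small_dbh)
  stems <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.census_columns, names(stems))
  if (length(missing_cols) > 0L) {
    stop("read_census(): '", path, "' lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_stems(stems, min_dbh_cm = min_dbh_cm,
                 on_small_dbh = on_small_dbh, source = path)
}

#' Validate a stem table and assemble individuals
#'
#' In-memory counterpart of [read_census()]: applies the same validation and
#' multi-stem aggregation to an already-loaded stem data frame.
#'
#' @param stems data frame with the census schema columns.
#' @inheritParams read_census
#' @param source label used in error messages.
#' @return As [read_census()].
#' @export
validate_stems <- function(stems, min_dbh_cm = 2.5,
                           on_small_dbh = c("error", "drop"),
                           source = "census") {
  on_small_dbh <- match.arg(on_small_dbh)
  stems$dbh_cm <- as.numeric(stems$dbh_cm)
  stems$height_m <- as.numeric(stems$height_m)

  bad_dbh <- which(is.na(stems$dbh_cm) | !is.finite(stems$dbh_cm) |
                     stems$dbh_cm <= 0)
  if (length(bad_dbh) > 0L) {
    stop("validate_stems(): non-positive or missing dbh_cm in ", source,
         " at row(s) ", paste(utils::head(bad_dbh, 10L), collapse = ", "),
         call. = FALSE)
  }
  small <- which(stems$dbh_cm < min_dbh_cm)
  if (length(small) > 0L) {
    if (on_small_dbh == "error") {
      stop("validate_stems(): dbh_cm below the ", min_dbh_cm,
           " cm census threshold in ", source, " at row(s) ",
           paste(utils::head(small, 10L), collapse = ", "), call. = FALSE)
    }
    warning("validate_stems(): dropping ", length(small),
            " stem(s) below the ", min_dbh_cm, " cm threshold (rows ",
            paste(utils::head(small, 10L), collapse = ", "), ")",
            call. = FALSE)
    stems <- stems[-small, , drop = FALSE]
  }
  bad_form <- which(!(stems$growth_form %in% .growth_forms))
  if (length(bad_form) > 0L) {
    stop("validate_stems(): unknown growth_form in ", source, " at row(s) ",
         paste(utils::head(bad_form, 10L), collapse = ", "),
         "; expected one of ", paste(.growth_forms, collapse = ", "),
         call. = FALSE)
  }
  neg_h <- which(!is.na(stems$height_m) & stems$height_m <= 0)
  if (length(neg_h) > 0L) {
    stop("validate_stems(): non-positive height_m in ", source,
         " at row(s) ", paste(utils::head(neg_h, 10L), collapse = ", "),
         call. = FALSE)
  }

  key <- paste(stems$plot_id, stems$individual_id, sep = "\r")
  first <- !duplicated(key)
  # attributes must be constant within an individual
  for (col in c("growth_form", "species", "family")) {
    v <- stems[[col]]
    v[is.na(v)] <- ""
    if (any(tapply(v, key, function(x) length(unique(x))) > 1L)) {
      stop("validate_stems(): column '", col,
           "' differs across stems of one individual in ", source,
           call. = FALSE)
    }
  }
  individuals <- data.frame(
    plot_id = stems$plot_id[first],
    individual_id = stems$individual_id[first],
    growth_form = stems$growth_form[first],
    species = stems$species[first],
    family = stems$family[first],
    stringsAsFactors = FALSE
  )
  ord_key <- key[first]
  agg <- function(x, f) as.numeric(tapply(x, key, f)[ord_key])
  individuals$dbh_cm <- agg(stems$dbh_cm, function(d) sqrt(sum(d^2)))
  individuals$height_m <- as.numeric(tapply(stems$height_m, key, function(h) {
    h <- h[!is.na(h)]
    if (length(h) == 0L) NA_real_ else max(h)
  })[ord_key])
  individuals$n_stems <- as.integer(tapply(key, key, length)[ord_key])

  no_h <- individuals$growth_form %in% c("tree", "palm") &
    is.na(individuals$height_m)
  if (any(no_h)) {
    stop("validate_stems(): tree/palm individual(s) without any stem height: ",
         paste(utils::head(individuals$individual_id[no_h], 10L),
               collapse = ", "), call. = FALSE)
  }
  list(stems = stems, individuals = individuals)
}

#' Read plot metadata
#'
#' @param path CSV with columns `plot_id`, `site`, `belt` (low/mid/high),
#'   `altitude_m`, `area_ha` and optional `lat`, `lon`.
#' @param check_belts if `TRUE` (default), check that each plot's altitude
#'   falls in its belt's band (low 800-1100 m, mid 1900-2100 m,
#'   high 2700-2900 m) when both are given.
#' @return Validated plot data frame.
#' @export
read_plots <- function(path, check_belts = TRUE) {
  plots <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("plot_id", "site", "belt", "altitude_m", "area_ha")
  missing_cols <- setdiff(need, names(plots))
  if (length(missing_cols) > 0L) {
    stop("read_plots(): '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(plots$plot_id)) {
    stop("read_plots(): duplicated plot_id in ", path, call. = FALSE)
  }
  if (any(!is.finite(plots$area_ha)) || any(plots$area_ha <= 0)) {
    stop("read_plots(): area_ha must be positive", call. = FALSE)
  }
  if (any(!plots$belt %in% c("low", "mid", "high"))) {
    stop("read_plots(): belt must be one of low, mid, high", call. = FALSE)
  }
  if (check_belts) {
    bands <- list(low = c(800, 1100), mid = c(1900, 2100),
                  high = c(2700, 2900))
    for (i in seq_len(nrow(plots))) {
      b <- bands[[plots$belt[i]]]
      a <- plots$altitude_m[i]
      if (is.finite(a) && (a < b[1] || a > b[2])) {
        stop("read_plots(): plot ", plots$plot_id[i], " altitude ", a,
             " m outside its '", plots$belt[i], "' band [", b[1], ", ",
             b[2], "] m", call. = FALSE)
      }
    }
  }
  plots
}

#' Write a stem census table
#'
#' Inverse of [read_census()]; used by the synthetic-study generator.
#'
#' @param stems stem data frame in census schema.
#' @param path output CSV path.
#' @export
write_census <- function(stems, path) {
  utils::write.csv(stems[, .census_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
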