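# Readers and writers for the HMD single-age, single-year text dialect
# (Mx_1x1 / Deaths_1x1 / Exposures_1x1) and the package's internal long CSV.

#' Parse an HMD 1x1 table
#'
#' Reads text in the Human Mortality Database single-age single-year layout:
#' header/blank lines, then whitespace-delimited columns
#' `Year Age Female Male Total`. The age token `"110+"` maps to integer age
#' 110 with the open-interval flag set. Rows may appear in any order; the
#' result is ordered by (year, age). Missing values (`"."`) inside the parsed
#' range raise a typed error naming the (year, age) cell.
#'
#' @param text a file path, or a character vector of lines.
#' @param sex which column to extract: `"female"`, `"male"` or `"total"`.
#' @param population population code stored on the result.
#' @return a [mortality_surface()] of the requested sex.
#' @export
parse_hmd_table <- function(text, sex = c("female", "male", "total"),
                            population = "unknown") {
  sex <- match.arg(sex)
  lines <- if (length(text) == 1L) {
    if (!grepl("\n", text, fixed = TRUE) && file.exists(text))
      readLines(text)
    else strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  # skip preamble: everything up to and including the column-header row if
  # present, otherwise the first two header/blank lines
  hdr <- grep("^\\s*Year\\b", lines)
  first_data <- if (length(hdr)) hdr[1] + 1L else 3L
  if (first_data > length(lines))
    abort_rmicast("parse_error", "no data rows found")
  keep <- seq(first_data, length(lines))
  raw <- lines[keep]
  nonblank <- nzchar(trimws(raw))
  raw <- raw[nonblank]; lineno <- keep[nonblank]

  toks <- strsplit(trimws(raw), "\\s+")
  w <- lengths(toks)
  if (any(w != 5L))
    abort_rmicast("parse_error", sprintf(
      "malformed row at line %d: expected 5 columns, found %d",
      lineno[which(w != 5L)[1]], w[which(w != 5L)[1]]))
  tok <- matrix(unlist(toks), ncol = 5L, byrow = TRUE)

  year <- as.integer(tok[, 1])
  open <- grepl("\\+$", tok[, 2])
  age <- as.integer(sub("\\+$", "", tok[, 2]))
  col <- match(sex, c("female", "male", "total")) + 2L
  val_tok <- tok[, col]
  if (anyNA(year) || anyNA(age))
    abort_rmicast("parse_error", "non-numeric Year or Age token")

  ages <- sort(unique(age)); years <- sort(unique(year))
  miss <- val_tok == "."
  if (any(miss)) {
    i <- which(miss)[1]
    abort_rmicast("missing_data_error", sprintf(
      "missing value ('.') for year %d, age %d", year[i], age[i]))
  }
  val <- suppressWarnings(as.numeric(val_tok))
  if (anyNA(val))
    abort_rmicast("parse_error", sprintf(
      "non-numeric value at line %d", lineno[which(is.na(val))[1]]))
  if (length(years) > 1 && any(diff(years) != 1L))
    abort_rmicast("contiguity_error", "years are not contiguous")
  if (length(ages) > 1 && any(diff(ages) != 1L))
    abort_rmicast("contiguity_error", "ages are not contiguous")

  mat <- matrix(NA_real_, length(ages), length(years),
                dimnames = list(ages, years))
  mat[cbind(match(age, ages), match(year, years))] <- val
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    abort_rmicast("missing_data_error", sprintf(
      "no row for year %s, age %s", colnames(mat)[idx[2]],
      rownames(mat)[idx[1]]))
  }
  mortality_surface(mat, ages = ages, years = years, population = population,
                    sex = sex, open_interval = any(open))
}

#' Format three mortality surfaces as HMD 1x1 text
#'
#' Inverse of [parse_hmd_table()]: emits the two-line preamble, the column
#' header, and one row per (year, age) with full double precision so that
#' `parse_hmd_table(format_hmd_table(...))` regenerates the numeric content
#' exactly.
#'
#' @param female,male,total `mortality_surface` objects on identical grids.
#' @param title first preamble line.
#' @return a character vector of lines.
#' @export
format_hmd_table <- function(female, male, total = NULL,
                             title = "Death rates (period 1x1)") {
  if (is.null(total)) total <- female
  for (s in list(female, male, total)) validate_surface(s)
  if (!identical(female$ages, male$ages) || !identical(female$years, male$years))
    abort_rmicast("alignment_error", "surfaces must share age/year grids")
  ages <- female$ages; years <- female$years
  age_tok <- as.character(ages)
  if (female$open_interval) age_tok[length(age_tok)] <- paste0(max(ages), "+")
  rows <- character(length(ages) * length(years))
  i <- 0L
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  for (yi in seq_along(years)) for (ai in seq_along(ages)) {
    i <- i + 1L
    rows[i] <- paste(years[yi], age_tok[ai], fmt(female$rates[ai, yi]),
                     fmt(male$rates[ai, yi]), fmt(total$rates[ai, yi]))
  }
  c(title, "", "  Year          Age         Female       Male       Total", rows)
}

#' Write a mortality surface as internal long CSV
#'
#' The internal exchange format is a long CSV with columns
#' `population, sex, year, age, rate[, deaths, exposure]` (UTF-8, "." decimal)
#' so fixtures stay diff-able and synthetic and real data travel identically.
#'
#' @param s a `mortality_surface`.
#' @param path output file path.
#' @export
write_surface_csv <- function(s, path) {
  validate_surface(s)
  df <- data.frame(
    population = s$population, sex = s$sex,
    year = rep(s$years, each = length(s$ages)),
    age = rep(s$ages, times = length(s$years)),
    rate = as.vector(s$rates)
  )
  if (!is.null(s$deaths)) df$deaths <- as.vector(s$deaths)
  if (!is.null(s$exposures)) df$exposure <- as.vector(s$exposures)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mortality surface from internal long CSV
#'
#' @param path file path written by [write_surface_csv()].
#' @param open_interval logical flag for the last age.
#' @return a `mortality_surface`.
#' @export
read_surface_csv <- function(path, open_interval = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "sex", "year", "age", "rate")
  if (!all(need %in% names(df)))
    abort_rmicast("parse_error", paste("long CSV must have columns",
                                       paste(need, collapse = ", ")))
  ages <- sort(unique(df$age)); years <- sort(unique(df$year))
  pick <- function(col) {
    if (!col %in% names(df)) return(NULL)
    m <- matrix(NA_real_, length(ages), length(years))
    m[cbind(match(df$age, ages), match(df$year, years))] <- df[[col]]
    m
  }
  mortality_surface(pick("rate"), ages = ages, years = years,
                    deaths = pick("deaths"), exposures = pick("exposure"),
                    population = df$population[1], sex = df$sex[1],
                    open_interval = open_interval)
}
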