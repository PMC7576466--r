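#' Period life table
#'
#' Construct a validated period life table: age- and sex-indexed annual death
#' probabilities (`qx`), the mortality input of the Markov engine. Ages must
#' be contiguous within each sex and `qx` must lie in `[0, 1]`; the terminal
#' `qx` of each sex is forced to 1 so that the oldest modelled age is
#' absorbing.
#'
#' @param age integer ages in years.
#' @param sex sex codes, `"F"` or `"M"`, one per row.
#' @param qx annual death probabilities in `[0, 1]`.
#' @return An object of class `life_table`: a `data.frame` with columns
#'   `age`, `sex`, `qx` and attribute `max_age`.
#' @seealso [gompertz_life_table()], [read_life_table()], [annual_death_prob()]
#' @export
#' @examples
#' lt <- life_table(age = rep(60:64, 2),
#'                  sex = rep(c("F", "M"), each = 5),
#'                  qx  = rep(c(0.01, 0.012, 0.014, 0.016, 0.02), 2))
#' attr(lt, "max_age")
life_table <- function(age, sex, qx) {
  if (length(age) != length(sex) || length(age) != length(qx))
    stop("age, sex and qx must have equal length", call. = FALSE)
  if (!all(sex %in% c("F", "M")))
    stop("unknown sex code: ", paste(unique(setdiff(sex, c("F", "M"))), collapse = ", "),
         call. = FALSE)
  age <- as.integer(age)
  bad <- which(!is.finite(qx) | qx < 0 | qx > 1)
  if (length(bad))
    stop("qx out of [0,1] at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  tab <- data.frame(age = age, sex = as.character(sex), qx = as.numeric(qx),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$sex, tab$age), ]
  for (s in unique(tab$sex)) {
    a <- tab$age[tab$sex == s]
    if (anyDuplicated(a))
      stop("duplicated ages for sex ", s, call. = FALSE)
    if (length(a) > 1L && any(diff(a) != 1L))
      stop("non-contiguous ages for sex ", s, call. = FALSE)
    tab$qx[tab$sex == s & tab$age == max(a)] <- 1  # terminal age absorbing
  }
  ranges <- tapply(tab$age, tab$sex, range)
  if (length(ranges) == 2L && !identical(ranges[[1]], ranges[[2]]))
    stop("age range differs between sexes", call. = FALSE)
  rownames(tab) <- NULL
  structure(tab, max_age = max(tab$age), min_age = min(tab$age),
            class = c("life_table", "data.frame"))
}

#' Synthetic Gompertz period life table
#'
#' Generate a life table from a Gompertz mortality law, the standard
#' parametric model of adult mortality: hazard `h(x) = a * exp(b * x)`, so the
#' annual death probability is `qx = 1 - exp(-(a/b) * (exp(b*(x+1)) - exp(b*x)))`.
#' The defaults are calibrated so that the annual death probability at age 84
#' is about 0.05 for women and 0.08 for men, with a 10%/year log-hazard slope —
#' loosely representative of southern-European period mortality at advanced
#' ages. This synthetic table is the packaged default fixture; a real
#' national period life table can be substituted via [read_life_table()].
#'
#' @param a_female,a_male Gompertz level parameters (hazard at age 0).
#' @param b Gompertz slope (per year of age).
#' @param min_age,max_age age range of the table; `qx` at `max_age` is 1.
#' @return A [life_table()].
#' @export
#' @examples
#' lt <- gompertz_life_table()
#' subset(lt, age == 84)
gompertz_life_table <- function(a_female = 1.1e-5, a_male = 1.8e-5,
                                b = 0.10, min_age = 0, max_age = 110) {
  stopifnot(a_female > 0, a_male > 0, b > 0, max_age > min_age)
  ages <- min_age:max_age
  qx_g <- function(a) 1 - exp(-(a / b) * (exp(b * (ages + 1)) - exp(b * ages)))
  life_table(age = rep(ages, 2L),
             sex = rep(c("F", "M"), each = length(ages)),
             qx  = c(pmin(qx_g(a_female), 1), pmin(qx_g(a_male), 1)))
}

#' Packaged default life table
#'
#' The synthetic Gompertz table of [gompertz_life_table()] with its default
#' parameters; also shipped as a plain-text fixture in
#' `inst/extdata/gompertz_life_table_synthetic.tsv`.
#'
#' @return A [life_table()].
#' @export
default_life_table <- function() gompertz_life_table()

#' Read / write a period life table
#'
#' Delimited text with header columns `age`, `sex`, `qx` (tab- or
#' comma-separated; HMD-derived period tables reduced to these columns load
#' directly). Validation errors name the offending line of the file.
#'
#' @param path file path.
#' @return `read_life_table()` returns a [life_table()];
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(raw)))
    stop("life table must have columns age, sex, qx (got: ",
         paste(names(raw), collapse = ", "), ")", call. = FALSE)
  bad <- which(!is.finite(raw$qx) | raw$qx < 0 | raw$qx > 1)
  if (length(bad))
    stop("qx out of [0,1] in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "), " (header is line 1)", call. = FALSE)
  life_table(raw$age, raw$sex, raw$qx)
}

#' @param table a [life_table()].
#' @rdname read_life_table
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  utils::write.table(as.data.frame(table)[, c("age", "sex", "qx")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annual death probability with a mortality relative risk
#'
#' Looks up `qx` for the given age and sex (ages beyond the table clamp to
#' its terminal row) and applies a relative risk on the hazard scale,
#' `p = 1 - (1 - qx)^rr`, which keeps the result a valid probability for any
#' `rr > 0`. At `rr = 1` the table value is returned unchanged.
#'
#' @param age age(s) in years (vectorised).
#' @param sex `"F"` or `"M"`.
#' @param table a [life_table()].
#' @param rr mortality relative risk, `> 0`.
#' @return death probabilities in `[0, 1]`.
#' @export
#' @examples
#' annual_death_prob(84, "F", gompertz_life_table())
annual_death_prob <- function(age, sex, table, rr = 1) {
  stopifnot(inherits(table, "life_table"), length(sex) == 1L, sex %in% c("F", "M"))
  if (!is.numeric(rr) || length(rr) != 1L || rr <= 0)
    stop("relative risk must be a single value > 0", call. = FALSE)
  qx <- qx_vector(table, sex)
  min_age <- attr(table, "min_age")
  idx <- pmin(pmax(floor(age), min_age), attr(table, "max_age")) - min_age + 1L
  1 - (1 - qx[idx])^rr
}

# per-sex qx vector ordered by age (internal fast path)
qx_vector <- function(table, sex) {
  rows <- table$sex == sex
  if (!any(rows)) stop("life table has no rows for sex ", sex, call. = FALSE)
  table$qx[rows][order(table$age[rows])]
}

#' @export
print.life_table <- function(x, ...) {
  cat("Period life table: ages ", min(x$age), "-", max(x$age),
      ", sexes ", paste(unique(x$sex), collapse = "/"),
      " (", nrow(x), " rows)\n", sep = "")
  invisible(x)
}
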