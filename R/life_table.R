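#' Age-indexed life table of annual death probabilities
#'
#' Holds the baseline annual probability of death q(age) used by the cohort
#' model; the hazard-ratio adjustment for unexplained syncope is applied on
#' top of these values at run time, not stored here.
#'
#' @param entries `data.frame` with columns `age` (integer years, strictly
#'   increasing) and `annual_death_prob` (in \[0, 1\]).
#' @return An object of class `life_table`.
#' @seealso [synthetic_life_table()], [read_life_table()]
#' @export
life_table <- function(entries) {
  entries <- as.data.frame(entries)
  stop_if(!all(c("age", "annual_death_prob") %in% names(entries)),
          "'entries' needs columns age and annual_death_prob")
  stop_if(nrow(entries) < 2, "a life table needs at least two ages")
  stop_if(any(diff(entries$age) <= 0), "ages must be strictly increasing")
  stop_if(any(entries$annual_death_prob < 0 | entries$annual_death_prob > 1 |
                is.na(entries$annual_death_prob)),
          "annual death probabilities must lie in [0, 1]")
  structure(list(entries = entries[, c("age", "annual_death_prob")]),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  e <- x$entries
  cat(sprintf("Life table: ages %g-%g, q(%g) = %.4g, q(%g) = %.4g\n",
              min(e$age), max(e$age), min(e$age), e$annual_death_prob[1],
              max(e$age), e$annual_death_prob[nrow(e)]))
  invisible(x)
}

#' Look up the baseline annual death probability at (possibly fractional) ages
#'
#' Linear interpolation between tabulated integer ages; ages outside the
#' tabulated range are an error (the table must cover the whole model
#' horizon).
#'
#' @param lt a [life_table()].
#' @param age numeric vector of ages, years.
#' @return vector of annual death probabilities.
#' @export
lookup_death_prob <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  e <- lt$entries
  stop_if(any(age < min(e$age) - 1e-9 | age > max(e$age) + 1e-9),
          sprintf("age outside life-table range [%g, %g]",
                  min(e$age), max(e$age)))
  stats::approx(e$age, e$annual_death_prob, xout = age, rule = 2)$y
}

#' Read / write a life table as two-column delimited text
#'
#' Tab-delimited, header `age<TAB>annual_death_prob`, ages in integer years.
#'
#' @param path file path.
#' @return `read_life_table()` returns a [life_table()];
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  life_table(utils::read.delim(path, sep = "\t", header = TRUE))
}

#' @rdname read_life_table
#' @param lt a [life_table()].
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  e <- lt$entries
  e$annual_death_prob <- sprintf("%.10g", e$annual_death_prob)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a Gompertz-Makeham life table
#'
#' Annual death probability `q(age) = 1 - exp(-(a + b * exp(c * age)))`,
#' clamped to \[0, 1\]: a constant (Makeham) background hazard plus an
#' exponentially age-increasing (Gompertz) component, the standard two-term
#' description of adult all-cause mortality.
#'
#' @param a Makeham level (annual hazard), >= 0.
#' @param b Gompertz scale, >= 0.
#' @param c Gompertz slope (per year of age), > 0.
#' @param ages integer ages to tabulate.
#' @return a [life_table()].
#' @examples
#' synthetic_life_table(5e-4, 2.6e-5, 0.097, 55:95)
#' @export
synthetic_life_table <- function(a, b, c, ages = 40:110) {
  check_nonneg(a, "a"); check_nonneg(b, "b")
  stop_if(c <= 0, "'c' must be positive")
  hazard <- a + b * exp(c * ages)
  stop_if(any(!is.finite(hazard)), "hazard overflows over the requested ages")
  q <- pmin(1, pmax(0, 1 - exp(-hazard)))
  life_table(data.frame(age = ages, annual_death_prob = q))
}

#' The bundled synthetic mortality fixture
#'
#' A Gompertz-Makeham stand-in for the national (Portuguese) all-cause
#' mortality table, which is external to the package. Calibration: Makeham
#' level `a = 5e-4`, Gompertz slope `c = 0.097` per year, and the Gompertz
#' scale solved so that the baseline annual death probability at the cohort
#' start age is q(61) = 0.010; this rises to roughly 0.15 by age 90.
#' Swappable via the life-table file interface for runs against an official
#' table.
#'
#' @param ages integer ages to tabulate (default 40-110, covering the
#'   30-year lifetime horizon from age 61 with margin).
#' @return a [life_table()].
#' @export
default_life_table <- function(ages = 40:110) {
  a <- 5e-4; c <- 0.097
  b <- (-log(1 - 0.010) - a) / exp(c * 61) # anchors q(61) = 0.010
  synthetic_life_table(a, b, c, ages)
}
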