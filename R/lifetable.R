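# Age-indexed annual all-cause mortality. The model treats these rates as
# non-vascular background mortality; vascular deaths are modelled explicitly
# through the stroke states.

#' Generate a synthetic Gompertz life table
#'
#' Builds an age-indexed table of annual all-cause death probabilities from a
#' Gompertz hazard, `q(age) = 1 - exp(-a * exp(b * age))`, closed at the top
#' of the age range by forcing `q(max_age) = 1` so no cohort member outlives
#' the model horizon.  The defaults (`a = 2e-5`, `b = 0.1`) give annual
#' mortality of about 1.6\% at age 67 rising to about 16\% at 90,
#' resembling recent UK national all-cause rates at these ages.
#'
#' @param a Gompertz level parameter (> 0).
#' @param b Gompertz slope per year of age (> 0).
#' @param start_age,max_age integer age range covered (inclusive).
#' @return A `data.frame` with columns `age` and `q` (annual death
#'   probability), one row per integer age.
#' @examples
#' lt <- generate_life_table()
#' lt[lt$age %in% c(67, 80, 100), ]
#' @export
generate_life_table <- function(a = 2e-5, b = 0.1, start_age = 67,
                                max_age = 100) {
  if (a <= 0 || b <= 0) stop("Gompertz parameters must be positive",
                             call. = FALSE)
  if (start_age >= max_age) stop("start_age must be below max_age",
                                 call. = FALSE)
  age <- seq.int(start_age, max_age)
  q <- pmin(1, 1 - exp(-a * exp(b * age)))
  q[length(q)] <- 1
  validate_life_table(data.frame(age = age, q = q))
}

#' Read a life table from a delimited text file
#'
#' Expects two columns, `age` and `q` (annual probability of death), with a
#' header row; whitespace- or tab-delimited.
#'
#' @param path path to the file.
#' @return A validated life-table `data.frame`.
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path,
                               call. = FALSE)
  lt <- utils::read.table(path, header = TRUE)
  if (!all(c("age", "q") %in% names(lt)))
    stop("life table must have columns 'age' and 'q'", call. = FALSE)
  validate_life_table(lt[, c("age", "q")])
}

#' @rdname load_life_table
#' @param lt a life-table `data.frame`.
#' @export
save_life_table <- function(lt, path) {
  lt <- validate_life_table(lt)
  utils::write.table(format(lt, digits = 17, scientific = FALSE), path,
                     quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

validate_life_table <- function(lt) {
  if (any(is.na(lt$age)) || any(lt$age != round(lt$age)))
    stop("life-table ages must be integers", call. = FALSE)
  if (any(diff(lt$age) != 1))
    stop("life table must cover consecutive integer ages", call. = FALSE)
  if (any(is.na(lt$q)) || any(lt$q < 0) || any(lt$q > 1))
    stop("life-table q values must lie in [0, 1]", call. = FALSE)
  if (lt$q[nrow(lt)] != 1)
    stop("life table must close with q = 1 at its top age", call. = FALSE)
  lt$age <- as.integer(lt$age)
  rownames(lt) <- NULL
  lt
}

# q at a given age; errors if the age is outside the table.
lookup_q <- function(life_table, age) {
  i <- match(age, life_table$age)
  if (any(is.na(i))) stop("age ", paste(age[is.na(i)], collapse = ", "),
                          " outside life-table range", call. = FALSE)
  life_table$q[i]
}
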