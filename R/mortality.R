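#' Life table of annual death probabilities
#'
#' @param ages contiguous ascending integer ages.
#' @param qx annual probability of dying before the next birthday, one per
#'   age, all in `[0, 1]`.
#' @return an object of class `ahc_life_table`.
#' @export
life_table <- function(ages, qx) {
  if (length(ages) != length(qx) || !length(ages)) {
    stop_ahc("life_table: ages and qx must be non-empty and equal length")
  }
  if (any(diff(ages) != 1L)) {
    stop_ahc("life_table: ages must be contiguous ascending integers")
  }
  if (any(!is.finite(qx)) || any(qx < 0 | qx > 1)) {
    stop_ahc("life_table: qx outside [0, 1]")
  }
  structure(list(ages = as.integer(ages), qx = as.numeric(qx)),
            class = "ahc_life_table")
}

#' @export
print.ahc_life_table <- function(x, ...) {
  cat(sprintf("<ahc_life_table ages %d-%d, qx %.5f-%.5f>\n",
              min(x$ages), max(x$ages), min(x$qx), max(x$qx)))
  invisible(x)
}

#' Read/write a life table as CSV (`age,qx`)
#'
#' @param path CSV file with columns `age` and `qx`, one row per integer age.
#' @return an `ahc_life_table`.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df))) {
    stop_ahc("life-table file must have columns 'age' and 'qx'")
  }
  life_table(df$age, df$qx)
}

#' @rdname read_life_table
#' @param lt an `ahc_life_table`.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(data.frame(age = lt$ages, qx = lt$qx), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# annual death probability at given ages, error on coverage gaps
qx_at <- function(lt, ages) {
  idx <- match(ages, lt$ages)
  if (anyNA(idx)) {
    stop_ahc("life table does not cover age(s) %s",
             paste(ages[is.na(idx)], collapse = ", "))
  }
  lt$qx[idx]
}

#' Apply the excess mortality of adults with intellectual disability
#'
#' The population carries roughly threefold mortality relative to the
#' general population. The default scales each annual probability,
#' `min(1, multiplier * qx)`; `method = "hazard"` scales on the hazard
#' scale, `1 - (1 - qx)^multiplier`, as a sensitivity alternative.
#'
#' @param lt an `ahc_life_table`.
#' @param multiplier positive mortality multiplier (3 in the base case).
#' @param method `"probability"` or `"hazard"`.
#' @return the adjusted `ahc_life_table`.
#' @export
adjust_id_mortality <- function(lt, multiplier,
                                method = c("probability", "hazard")) {
  method <- match.arg(method)
  if (!is_number(multiplier) || multiplier <= 0) {
    stop_ahc("multiplier must be a positive number")
  }
  qx <- switch(method,
    probability = pmin(1, multiplier * lt$qx),
    hazard = 1 - (1 - lt$qx)^multiplier
  )
  life_table(lt$ages, qx)
}

#' Cohort survival curve from a life table
#'
#' @param lt an `ahc_life_table` covering `[start_age, age_cap]`.
#' @param start_age cohort starting age.
#' @param age_cap terminal age (death is certain beyond it).
#' @return an `ahc_survival_curve`: `start_age` and `values`, the probability
#'   of being alive at the beginning of each annual cycle
#'   (`values[1] = 1`, length `age_cap - start_age + 1`, non-increasing).
#' @export
survival_curve <- function(lt, start_age, age_cap) {
  if (age_cap <= start_age) stop_ahc("age_cap must exceed start_age")
  q <- qx_at(lt, start_age:(age_cap - 1))
  values <- c(1, cumprod(1 - q))
  structure(list(start_age = start_age, values = values),
            class = "ahc_survival_curve")
}

#' @export
print.ahc_survival_curve <- function(x, ...) {
  cat(sprintf("<ahc_survival_curve from age %d, %d cycles, S(end)=%.4g>\n",
              x$start_age, length(x$values) - 1L, x$values[length(x$values)]))
  invisible(x)
}
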