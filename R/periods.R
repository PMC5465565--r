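#' Fifteen developmental periods of the human brain
#'
#' Age bins from embryonic development (4 post-conception weeks, PCW)
#' through late adulthood (60+ years). Prenatal ages (periods 1--7) are
#' expressed in PCW; postnatal ages (periods 8--15) in months or years.
#' The two scales are never converted into each other: the age unit selects
#' the prenatal or postnatal block. All intervals are half-open
#' \code{[lower, upper)}; period 15 is unbounded above. The late-fetal
#' period runs 24--38 PCW (upper bound taken as term birth).
#'
#' @format data.frame with columns period, description, lower, upper, unit.
#' @export
developmentalPeriods <- function() {
  data.frame(
    period = 1:15,
    description = c("Embryonic", "Early fetal", "Early fetal",
                    "Early mid-fetal", "Early mid-fetal", "Late mid-fetal",
                    "Late fetal", "Neonatal and early infancy",
                    "Late infancy", "Early childhood",
                    "Middle and late childhood", "Adolescence",
                    "Young adulthood", "Middle adulthood", "Late adulthood"),
    lower = c(4, 8, 10, 13, 16, 19, 24, 0, 0.5, 1, 6, 12, 20, 40, 60),
    upper = c(8, 10, 13, 16, 19, 24, Inf, 0.5, 1, 6, 12, 20, 40, 60, Inf),
    unit = c(rep("PCW", 7), rep("Y", 8)),
    stringsAsFactors = FALSE)
}

.PRENATAL_BREAKS <- c(4, 8, 10, 13, 16, 19, 24)         # PCW, periods 1..7
.POSTNATAL_BREAKS <- c(0, 0.5, 1, 6, 12, 20, 40, 60)    # years, periods 8..15

#' Assign a developmental period from age
#'
#' Maps an age to one of the 15 developmental periods. Prenatal ages are in
#' post-conception weeks (\code{"PCW"}, must be >= 4); postnatal ages in
#' months (\code{"M"}) or years (\code{"Y"}). Intervals are half-open
#' \code{[lower, upper)}, so e.g. 8 PCW falls in period 2 and 6 months in
#' period 9.
#'
#' @param ageValue numeric vector of non-negative ages.
#' @param ageUnit character vector, \code{"PCW"}, \code{"M"} or \code{"Y"}
#'   (recycled against \code{ageValue}).
#' @return integer vector of periods in 1..15.
#' @examples
#' assignPeriod(6, "PCW")   # 1, embryonic
#' assignPeriod(3, "M")     # 8, neonatal / early infancy
#' assignPeriod(25, "Y")    # 13, young adulthood
#' @export
assignPeriod <- function(ageValue, ageUnit) {
  ageValue <- as.numeric(ageValue)
  ageUnit <- toupper(trimws(as.character(ageUnit)))
  n <- max(length(ageValue), length(ageUnit))
  ageValue <- rep_len(ageValue, n)
  ageUnit <- rep_len(ageUnit, n)
  if (anyNA(ageValue) || any(ageValue < 0))
    stop("age values must be non-negative numbers")
  bad <- !ageUnit %in% .AGE_UNITS
  if (any(bad))
    stop("unknown age unit(s): ", paste(unique(ageUnit[bad]), collapse = ", "))
  out <- integer(n)
  pre <- ageUnit == "PCW"
  if (any(pre)) {
    if (any(ageValue[pre] < 4))
      stop("PCW ages below 4 are pre-embryonic and cannot be assigned a period")
    out[pre] <- findInterval(ageValue[pre], .PRENATAL_BREAKS)
  }
  if (any(!pre)) {
    yrs <- ageValue[!pre] / ifelse(ageUnit[!pre] == "M", 12, 1)
    out[!pre] <- 7L + findInterval(yrs, .POSTNATAL_BREAKS)
  }
  out
}
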