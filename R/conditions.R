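#' The five thermal stimulation conditions
#'
#' Returns the condition table used throughout the package: the five
#' thermal stimuli ordered cold-to-hot with their intensity group
#' (NOX = very intense, MOD = moderately intense, INNO = innocuous), the
#' mean and SD of the 0-9 thermal-sensation ratings, and the object
#' temperature bin in degrees Celsius. Bins are mutually disjoint; the gaps
#' between bins (e.g. 15-16 C) are not part of any condition.
#'
#' @return data.frame with columns `name`, `group`, `discomfort_mean`,
#'   `discomfort_sd`, `temp_low_c`, `temp_high_c`, ordered cold to hot.
#' @examples
#' thermalConditions()
#' @export
thermalConditions <- function() {
  data.frame(
    name = c("very_cold", "cold", "warm", "hot", "very_hot"),
    group = c("NOX", "MOD", "INNO", "MOD", "NOX"),
    discomfort_mean = c(6.6, 4.5, 2.6, 3.9, 5.9),
    discomfort_sd = c(0.48, 0.5, 0.48, 0.3, 0.83),
    temp_low_c = c(10, 16, 25, 35, 40.99),
    temp_high_c = c(14.99, 24.99, 33, 40, 44.99),
    stringsAsFactors = FALSE
  )
}

.conditionRow <- function(condition) {
  tab <- thermalConditions()
  i <- match(condition, tab$name)
  if (is.na(i))
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(tab$name, collapse = ", "))
  tab[i, , drop = FALSE]
}

#' Intensity group of a condition
#'
#' @param condition one of `"very_cold"`, `"cold"`, `"warm"`, `"hot"`,
#'   `"very_hot"`.
#' @return `"NOX"`, `"MOD"` or `"INNO"`.
#' @export
conditionGroup <- function(condition) {
  vapply(condition, function(cn) .conditionRow(cn)$group, character(1),
         USE.NAMES = FALSE)
}

#' Map a temperature to its thermal condition
#'
#' Assigns a temperature in degrees Celsius to the condition whose bin
#' contains it. Temperatures falling in the gaps between bins are, by
#' default, assigned to the nearest bin boundary and flagged; with
#' `gap = "unresolved"` they return `NA`.
#'
#' @param tempC numeric temperatures in degrees Celsius (finite).
#' @param gap `"nearest"` (default) or `"unresolved"`.
#' @return data.frame with columns `temp_c`, `condition`, `group`,
#'   `in_gap` (logical).
#' @examples
#' tempToClass(12)    # very_cold, NOX
#' tempToClass(28)    # warm, INNO
#' tempToClass(15.5)  # gap: nearest boundary, flagged
#' @export
tempToClass <- function(tempC, gap = c("nearest", "unresolved")) {
  gap <- match.arg(gap)
  if (any(!is.finite(tempC))) stop("temperatures must be finite")
  tab <- thermalConditions()
  assign1 <- function(t) {
    inside <- which(t >= tab$temp_low_c & t <= tab$temp_high_c)
    if (length(inside)) return(c(tab$name[inside[1]], FALSE))
    if (gap == "unresolved") return(c(NA_character_, TRUE))
    # distance to the nearest bin boundary
    d <- pmin(abs(t - tab$temp_low_c), abs(t - tab$temp_high_c))
    c(tab$name[which.min(d)], TRUE)
  }
  res <- t(vapply(tempC, assign1, character(2)))
  cond <- res[, 1]
  data.frame(
    temp_c = tempC,
    condition = cond,
    group = ifelse(is.na(cond), NA_character_,
                   tab$group[match(cond, tab$name)]),
    in_gap = as.logical(res[, 2]),
    stringsAsFactors = FALSE
  )
}

#' Withdrawal speed policy for an intensity group
#'
#' The reflex policy of the robotic arm: fast withdrawal for very intense
#' (NOX) stimuli, slow for moderately intense (MOD), delayed (very slow)
#' for innocuous (INNO).
#'
#' @param group `"NOX"`, `"MOD"` or `"INNO"` (vectorized).
#' @return `"fast"`, `"slow"` or `"delayed"`.
#' @examples
#' withdrawalPolicy("NOX")
#' @export
withdrawalPolicy <- function(group) {
  map <- c(NOX = "fast", MOD = "slow", INNO = "delayed")
  bad <- setdiff(unique(group), names(map))
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "),
         "; expected NOX, MOD or INNO")
  unname(map[group])
}

#' Standard 64-channel montage labels
#'
#' Channel labels of the extended 10/20 (5%) system used by the synthetic
#' generator's default 64-electrode montage.
#'
#' @return character vector of 64 unique labels.
#' @export
montage64 <- function() {
  c("Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2",
    "FT9", "FT10", "Iz")
}
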