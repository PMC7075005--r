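#' Veber oral-bioavailability rule
#'
#' A compound is predicted orally bioavailable when it has at most 10
#' rotatable bonds and a topological polar surface area of at most 140
#' square Angstroms. Both boundaries are inclusive.
#'
#' @param rotatable_bonds non-negative integer count(s).
#' @param tpsa non-negative topological polar surface area(s), in Angstrom^2.
#' @return Logical vector: `TRUE` where both criteria hold.
#' @export
#' @examples
#' veber_pass(10, 140)   # boundary compounds pass
#' veber_pass(11, 100)
veber_pass <- function(rotatable_bonds, tpsa) {
  if (length(rotatable_bonds) != length(tpsa)) {
    stop("descriptor vectors must have the same length", call. = FALSE)
  }
  bad <- is.na(rotatable_bonds) | is.na(tpsa) |
    !is.finite(rotatable_bonds) | !is.finite(tpsa) |
    rotatable_bonds < 0 | tpsa < 0
  if (any(bad)) {
    stop("invalid descriptor value(s) at position(s) ",
         paste(which(bad), collapse = ", "),
         ": descriptors must be non-negative and finite", call. = FALSE)
  }
  rotatable_bonds <= 10 & tpsa <= 140
}

#' Screen a compound table with Veber's filter
#'
#' Applies [veber_pass()] to every record and reports, per compound, which
#' criterion failed (`"none"`, `"bonds"`, `"tpsa"` or `"both"`). Input order
#' is preserved; compounds with missing or negative descriptors raise an
#' error naming them rather than being silently dropped.
#'
#' @param records data frame as returned by [read_compound_table()] (columns
#'   `compound_id`, `rotatable_bonds`, `tpsa` at minimum).
#' @return A list with `passing` (the subset of `records` that pass) and
#'   `report`, itself a list with `n_input`, `n_pass` and `flags` (a data
#'   frame with `compound_id`, `pass`, `failed`).
#' @export
screen_compounds <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "rotatable_bonds", "tpsa") %in%
                  names(records)))
  if (nrow(records) == 0) {
    return(list(passing = records,
                report = list(n_input = 0L, n_pass = 0L,
                              flags = data.frame(compound_id = character(),
                                                 pass = logical(),
                                                 failed = character(),
                                                 stringsAsFactors = FALSE))))
  }
  rb <- records$rotatable_bonds
  tp <- records$tpsa
  bad <- is.na(rb) | is.na(tp) | !is.finite(rb) | !is.finite(tp) |
    rb < 0 | tp < 0
  if (any(bad)) {
    stop("invalid descriptors for compound(s): ",
         paste(records$compound_id[bad], collapse = ", "), call. = FALSE)
  }
  ok_b <- rb <= 10
  ok_t <- tp <= 140
  pass <- ok_b & ok_t
  failed <- ifelse(pass, "none",
                   ifelse(!ok_b & !ok_t, "both",
                          ifelse(!ok_b, "bonds", "tpsa")))
  flags <- data.frame(compound_id = records$compound_id,
                      pass = pass, failed = failed,
                      stringsAsFactors = FALSE)
  list(passing = records[pass, , drop = FALSE],
       report = list(n_input = nrow(records), n_pass = sum(pass),
                     flags = flags))
}
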