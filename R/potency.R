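# Potency arithmetic on the congeneric series: relative potency changes
# against a reference compound, and the mean potency gap between the two
# binding sites.

#' Relative potency change against a reference compound
#'
#' Computes Delta_i = activity_i - activity_reference (log units) for every
#' compound in the table. Compounds with a missing activity get a missing
#' Delta.
#'
#' @param records compound table (see \code{\link{loadCompoundTable}}).
#' @param referenceId compound_id of the reference (e.g. the unsubstituted
#'   scaffold).
#' @param column activity column, "pEC50_a1b3" or "pKi_a1g2".
#' @return named numeric vector (names are compound ids), NA where the
#'   activity is missing.
#' @export
relativePotency <- function(records, referenceId,
                            column = c("pEC50_a1b3", "pKi_a1g2")) {
  column <- match.arg(column)
  idx <- match(referenceId, records$compound_id)
  if (is.na(idx)) stop("unknown reference compound id: ", referenceId)
  ref <- records[[column]][idx]
  if (!is.finite(ref)) {
    stop("reference compound ", referenceId, " has no value in ", column)
  }
  out <- records[[column]] - ref
  names(out) <- records$compound_id
  out
}

#' Mean potency gap between the two binding sites
#'
#' Mean over compounds measured at both sites of (pKi_a1g2 - pEC50_a1b3),
#' i.e. the average log-unit potency advantage of the alpha1+/gamma2- over
#' the alpha1+/beta3- site.
#'
#' @param records compound table.
#' @return list with \code{mean} (log units), \code{n} (compounds used) and
#'   \code{gaps} (per-compound values).
#' @export
meanSiteDifference <- function(records) {
  both <- is.finite(records$pEC50_a1b3) & is.finite(records$pKi_a1g2)
  if (!any(both)) stop("no compound has both activities")
  gaps <- records$pKi_a1g2[both] - records$pEC50_a1b3[both]
  names(gaps) <- records$compound_id[both]
  list(mean = mean(gaps), n = sum(both), gaps = gaps)
}
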