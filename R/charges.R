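# Fragment partial-charge assembly: the probe's charges are derived per
# fragment (the neutral PDT-BODIPY part and the +1 TPP part) and merged into
# one per-atom set whose total must equal the molecular charge.

#' Per-fragment partial charges
#'
#' @param fragment_id Fragment label, e.g. "TPP" or "PDT-BODIPY".
#' @param charges Named numeric vector of per-atom partial charges (e);
#'   names are atom ids, unique within the fragment.
#' @param total Declared fragment total charge (e); defaults to the rounded
#'   sum of `charges`.
#' @return Object of class `fragment_charges`.
#' @export
fragment_charges <- function(fragment_id, charges, total = NULL) {
  stopifnot(is.numeric(charges))
  if (length(charges) && is.null(names(charges))) {
    stop("charges must be a named vector (atom ids)")
  }
  if (anyDuplicated(names(charges))) {
    stop("duplicate atom ids within fragment ", fragment_id)
  }
  if (is.null(total)) total <- round(sum(charges))
  structure(list(fragment_id = fragment_id, charges = charges,
                 total = as.numeric(total)),
            class = "fragment_charges")
}

#' Merge fragment charge sets into one molecule
#'
#' Atom ids shared between fragments are junction atoms and take the mean of
#' their fragment values. The merged total is compared with the sum of the
#' declared fragment totals (for the probe: +1 e from TPP, 0 from the
#' PDT-BODIPY part); a deviation above `max_dev` (default 0.01 e) signals
#' inconsistent fragment charge sets and raises an error, otherwise the
#' residual is spread uniformly over all atoms so the total is restored
#' exactly.
#'
#' @param fragments List of [fragment_charges()].
#' @param max_dev Largest tolerated deviation of the raw merged total from
#'   the declared total (e).
#' @return List with `charges` (named numeric), `total` (the declared
#'   total), `raw_total`, and `junction_atoms`.
#' @examples
#' tpp <- fragment_charges("TPP", c(P1 = 0.6, C1 = 0.2, C2 = 0.2))
#' pdt <- fragment_charges("PDT-BODIPY", c(B1 = -0.3, N1 = 0.3), total = 0)
#' assemble_charges(list(tpp, pdt))$total
#' @export
assemble_charges <- function(fragments, max_dev = 0.01) {
  stopifnot(length(fragments) >= 1,
            all(vapply(fragments, inherits, TRUE, "fragment_charges")))
  all_names <- unlist(lapply(fragments, function(f) names(f$charges)))
  if (!length(all_names)) {
    stop("fragments contain no atoms; cannot assemble a charge set")
  }
  ids <- unique(all_names)
  acc <- matrix(NA_real_, length(ids), length(fragments),
                dimnames = list(ids, NULL))
  for (k in seq_along(fragments)) {
    f <- fragments[[k]]
    acc[names(f$charges), k] <- f$charges
  }
  merged <- rowMeans(acc, na.rm = TRUE)
  junction <- ids[rowSums(!is.na(acc)) > 1]
  target <- sum(vapply(fragments, `[[`, 0, "total"))
  raw <- sum(merged)
  if (abs(raw - target) > max_dev) {
    stop(sprintf(
      "assembled charge total %.4f e deviates from the declared %.4f e by more than %.3g e: inconsistent fragment charge sets",
      raw, target, max_dev))
  }
  merged <- merged + (target - raw) / length(merged)
  list(charges = merged, total = target, raw_total = raw,
       junction_atoms = junction)
}
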