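#' Additive relationship and household matrices from a pedigree
#'
#' Computes the additive (numerator) relationship matrix `A` (twice the
#' kinship coefficient) by the tabular method, proceeding from founders so
#' that each child's row is the average of its parents' rows, with the
#' diagonal inflated by half the parents' relationship. Monozygotic co-twin
#' entries are then set to 1, since MZ twins share their entire genome.
#' The household matrix `H` is a 0/1 block indicator of shared nuclear
#' family (parents included), used for the common-environment variance
#' component.
#'
#' @param ped Pedigree table from [generate_pedigree()].
#' @return A list of class `kinship_matrix`: `A` (additive relationship),
#'   `H` (household indicator), `id` (individual ids, matrix order) and
#'   `family` (family id per individual).
#' @export
additive_relationship <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  ord <- pedigree_order(ped)
  fi <- match(ped$father_id, ped$individual_id)
  mi <- match(ped$mother_id, ped$individual_id)

  A <- matrix(0, n, n)
  for (i in ord) {
    if (is.na(fi[i])) {
      A[i, i] <- 1
    } else {
      f <- fi[i]; m <- mi[i]
      v <- 0.5 * (A[f, ] + A[m, ])
      v[i] <- 0
      A[i, ] <- v
      A[, i] <- v
      A[i, i] <- 1 + 0.5 * A[f, m]
    }
  }

  for (lab in unique(stats::na.omit(ped$twin_pair))) {
    tw <- which(!is.na(ped$twin_pair) & ped$twin_pair == lab)
    if (ped$zygosity[tw[1]] == "MZ_twin") {
      A[tw[1], tw[2]] <- A[tw[2], tw[1]] <- 1
      # an MZ twin relates to everyone exactly as its co-twin does
      others <- setdiff(seq_len(n), tw)
      shared <- pmax(A[tw[1], others], A[tw[2], others])
      A[tw[1], others] <- A[tw[2], others] <- shared
      A[others, tw[1]] <- A[others, tw[2]] <- shared
    }
  }

  H <- outer(ped$family_id, ped$family_id, "==") * 1
  dimnames(A) <- dimnames(H) <- list(ped$individual_id, ped$individual_id)
  structure(list(A = A, H = H, id = ped$individual_id,
                 family = ped$family_id), class = "kinship_matrix")
}
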