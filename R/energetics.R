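## Direct energetic cost of dsDNA viral genome replication.
##
## For a double-stranded DNA genome of per-strand length L_g bases, the
## direct cost per virion genome is approximated as
##     E_rep ~= 2 L_g (e_d + e_p)
## ATP-equivalent hydrolysis events, where e_d is the average cost of
## synthesizing one DNA nucleotide from precursor metabolites (~11 ATP
## equivalents) and e_p the chain-elongation cost per base (~2 ATP
## equivalents). The factor 2 carries the double-strandedness; L_g is the
## per-strand base count, so a genome quoted as "194 kb" enters as
## L_g = 194000, not twice that.

#' Replication cost of a dsDNA viral genome
#'
#' @param lengthBases per-strand genome length \eqn{L_g} (bases, > 0).
#' @param eD ATP-equivalents per nucleotide for precursor synthesis
#'   (default 11).
#' @param eP ATP-equivalents per nucleotide for chain elongation
#'   (default 2).
#' @return Direct replication cost in ATP-equivalents per virion genome:
#'   \code{2 * lengthBases * (eD + eP)}. Linear in \code{lengthBases} and
#'   exact in integer arithmetic for integer inputs.
#' @examples
#' replicationCost(194000)
#' @export
replicationCost <- function(lengthBases, eD = 11, eP = 2) {
  if (any(lengthBases <= 0)) stop("lengthBases must be > 0")
  if (eD < 0 || eP < 0) stop("per-nucleotide costs must be >= 0")
  2 * lengthBases * (eD + eP)
}

#' Replication-cost difference between two genome lengths
#'
#' Absolute difference in direct replication cost; depends only on the
#' length difference (translation invariance). A 12 kb difference at the
#' default per-nucleotide costs amounts to 312,000 ATP-equivalents per
#' genome.
#'
#' @param lengthA,lengthB per-strand genome lengths (bases, > 0).
#' @param eD,eP per-nucleotide costs as in [replicationCost()].
#' @return ATP-equivalents per genome.
#' @examples
#' costDifference(194000, 182000)
#' @export
costDifference <- function(lengthA, lengthB, eD = 11, eP = 2) {
  abs(replicationCost(lengthA, eD, eP) - replicationCost(lengthB, eD, eP))
}
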