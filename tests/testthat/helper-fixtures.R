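# shared fixture helpers: everything is generated in code at test time

# render a lone silhouette (disk if arms = 0) plus its nucleus channel
render_single_cell <- function(r0, arms = 0, amp = 0, phase = 0, side = 61) {
  ctr <- (side + 1) / 2
  dic <- matrix(0.05, side, side)
  nuc <- matrix(0.05, side, side)
  dic[hemoquant:::.cell_pixels(c(side, side), ctr, ctr, r0, arms, amp,
                               phase)] <- 0.7
  nuc[hemoquant:::.cell_pixels(c(side, side), ctr, ctr, 3.5, 0, 0, 0)] <- 0.9
  list(dic = dic, nuc = nuc)
}

# match measured cell records to ground-truth records by nearest centre
match_to_truth <- function(est, truth) {
  vapply(seq_len(nrow(est)), function(i)
    which.min((truth$center_row - est$center_row[i])^2 +
              (truth$center_col - est$center_col[i])^2), integer(1))
}

# the seven printed best-pose energies and inhibition constants (uM) from
# the fatty-acid docking screen shipped in extdata
printed_affinities <- function() {
  data.frame(
    ligand = c("Arachidonic acid", "Caffeic acid", "Ferulic acid",
               "Linoleic acid", "Linolenic acid", "Palmitic acid",
               "p-Coumarate"),
    energy = c(-8.06, -6.40, -6.47, -6.37, -8.35, -8.69, -6.41),
    ki_uM = c(1.23, 20.27, 18.03, 21.39, 0.72, 0.43, 19.92))
}
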