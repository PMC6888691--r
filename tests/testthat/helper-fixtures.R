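# assemble a phase_space by hand, bypassing the generator
make_phase_space <- function(x, y, z, energy,
                             process = rep("ionization", length(x)),
                             target_dose = 1) {
  structure(
    list(deposits = data.frame(x = x, y = y, z = z, energy = energy,
                               process = process,
                               track_id = seq_along(x),
                               stringsAsFactors = FALSE),
         seed = 0L, config_digest = "manual", target_dose = target_dose),
    class = "phase_space"
  )
}

# independent DSB-clustering oracle: SSBs are nodes, any pair within the
# base-pair threshold is an edge, clusters are connected components; a
# component with >= 2 members spanning both strands is one DSB
oracle_dsb_count <- function(ssbs, bp_threshold) {
  n <- nrow(ssbs)
  if (n == 0) return(0L)
  adj <- abs(outer(ssbs$bp_index, ssbs$bp_index, `-`)) <= bp_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  sum(vapply(split(ssbs$strand, comp), function(s)
    length(s) >= 2 && length(unique(s)) == 2, logical(1)))
}

random_ssbs <- function(n, n_bp) {
  data.frame(strand = sample(0:1, n, replace = TRUE),
             bp_index = sample(0:(n_bp - 1), n, replace = TRUE))
}

table2_slopes <- c(control = 17.47e-5, au = 23.49e-5, aupt = 33.18e-5,
                   control_dmso = 2.91e-5, au_dmso = 3.56e-5,
                   aupt_dmso = 4.14e-5)
gel_doses <- seq(0, 500, by = 100)

noiseless_lanes <- function(m_dsb, staining_factor = 1.47)
  synth_gel(gel_doses, m_dsb, noise_sd = 0, replicates = 3, seed = 1L,
            staining_factor = staining_factor)
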