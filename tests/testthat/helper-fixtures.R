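# Shared fixtures: a small encoder configuration and helpers to build
# hand-permuted molecular graphs.

desk_config <- function(...) {
  encoder_config(embed_dim = 8L, protein_channels = rep(8L, 3),
                 protein_kernel_sizes = c(3L, 5L, 7L),
                 drug_hidden_dims = rep(8L, 3), fusion_dim = 16L,
                 attention_rank = 4L, head_hidden = 8L, disc_hidden = 8L,
                 l_max = 200L, ...)
}

# apply an atom permutation to a molecular_graph: node i of the output is
# node perm[i] of the input
permute_graph <- function(graph, perm) {
  inv <- order(perm)
  edges <- graph$edges
  if (nrow(edges)) {
    edges <- cbind(inv[edges[, 1]], inv[edges[, 2]])
    edges <- t(apply(edges, 1, sort))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(node_features = graph$node_features[perm, , drop = FALSE],
                 edges = edges, n_atoms = graph$n_atoms,
                 smiles = graph$smiles),
            class = "molecular_graph")
}

rand_params_bilinear <- function(c, h, r, f) {
  list(U = rand_mat(c, r), V = rand_mat(h, r),
       Uf = rand_mat(c, f), Vf = rand_mat(h, f))
}
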