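#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
NULL

# Amino-acid vocabulary: the 20 canonical residues plus the ambiguity /
# rare-residue codes X, B, Z, U, O. Anything else becomes X before encoding.
.aa_valid <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "B", "Z", "U", "O")

#' Tokenize a protein sequence
#'
#' Maps a protein sequence to integer tokens with the fixed alphabetical table
#' A = 1, ..., Z = 26 (so the padding token 0 is never produced by a residue).
#' Characters outside the accepted vocabulary (the 20 canonical residues plus
#' X, B, Z, U, O) are mapped to X first. Sequences longer than `l_max` keep
#' their N-terminal prefix.
#'
#' @param sequence Character scalar, the amino-acid sequence.
#' @param l_max Maximum kept length (default 1200).
#' @param pad If `TRUE`, right-pad the token vector with 0 up to `l_max`.
#' @return A list with `tokens` (integer vector) and `length` (pre-padding
#'   length after truncation).
#' @export
tokenize_protein <- function(sequence, l_max = 1200L, pad = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) abort("empty protein sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars[!chars %in% .aa_valid] <- "X"
  if (length(chars) > l_max) chars <- chars[seq_len(l_max)]
  tokens <- match(chars, LETTERS)
  len <- length(tokens)
  if (pad && len < l_max) tokens <- c(tokens, integer(l_max - len))
  list(tokens = as.integer(tokens), length = len)
}

# strip padding; returns the integer tokens actually encoding residues
active_tokens <- function(tok) tok$tokens[seq_len(tok$length)]

.element_list <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")
.max_degree <- 5L

atom_feature_dim <- function() length(.element_list) + 1L + (.max_degree + 1L) + 2L

# Light syntactic screen applied before handing a string to OpenBabel, which
# silently "repairs" some malformed inputs (e.g. an unclosed branch).
check_smiles_syntax <- function(smiles) {
  if (!nzchar(smiles)) return(FALSE)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  if (cumsum(chars == "(")[length(chars)] != sum(chars == ")")) return(FALSE)
  if (any(cumsum(chars == ")") > cumsum(chars == "("))) return(FALSE)
  if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
  # ring-closure digits must come in pairs
  digits <- gsub("%[0-9]{2}", "", smiles)
  digits <- gsub("\\[[^]]*\\]", "", digits) # isotopes/charges inside brackets
  counts <- table(strsplit(gsub("[^0-9]", "", digits), "")[[1]])
  all(counts %% 2 == 0)
}

#' Build a molecular graph from a SMILES string
#'
#' Parses the SMILES (via ChemmineR/OpenBabel), keeping one node per heavy
#' atom. Node features are the concatenation of a one-hot element encoding
#' (C, N, O, S, F, Cl, Br, I, P, other), a one-hot heavy-atom degree
#' (0..5, capped), the formal charge, and an aromatic flag. Edges are the
#' covalent bonds, stored once as undirected pairs without self-loops.
#'
#' @param smiles Character scalar.
#' @return An object of class `molecular_graph`: a list with `node_features`
#'   (num_atoms x feature_dim matrix), `edges` (two-column integer matrix),
#'   `n_atoms`, and the originating `smiles`.
#' @export
smiles_to_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!check_smiles_syntax(smiles)) {
    abort(paste0("cannot parse SMILES '", smiles, "'"))
  }
  sdf <- withCallingHandlers(
    tryCatch(ChemmineR::smiles2sdf(smiles),
             error = function(e) abort(paste0("cannot parse SMILES '", smiles, "'"))),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (length(sdf) < 1L) abort(paste0("cannot parse SMILES '", smiles, "'"))
  mol <- sdf[[1L]]
  ab <- tryCatch(ChemmineR::atomblock(mol), error = function(e) NULL)
  n <- if (is.null(ab)) 0L else nrow(ab)
  if (n < 1L) abort(paste0("cannot parse SMILES '", smiles, "' (no atoms)"))
  elements <- sub("_.*$", "", rownames(ab))

  bb <- ChemmineR::bondblock(mol)
  edges <- if (is.null(bb) || nrow(bb) == 0L) {
    matrix(integer(0), ncol = 2L)
  } else {
    e <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
    t(apply(e, 1L, sort)) # canonical order, undirected
  }
  if (nrow(edges) > 1L) edges <- unique(edges)

  degree <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)

  # old-style ctab charge codes in atom-block field 5 (4 = radical -> 0)
  code <- if (ncol(ab) >= 5L) as.integer(ab[, 5L]) else integer(n)
  code[is.na(code) | code < 0L | code > 7L] <- 0L
  charge <- c(0, 3, 2, 1, 0, -1, -2, -3)[code + 1L]

  aromatic <- rep(0, n)
  if (nrow(edges) > 0L) {
    rng <- tryCatch(
      suppressWarnings(ChemmineR::rings(mol, type = "all", arom = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(rng) && length(rng$RINGS) > 0L) {
      arom_rings <- rng$RINGS[which(rng$AROMATIC)]
      arom_atoms <- unique(unlist(lapply(arom_rings, function(r) {
        as.integer(sub("^.*_", "", r))
      })))
      aromatic[arom_atoms] <- 1
    }
  }

  el_idx <- match(elements, .element_list)
  el_idx[is.na(el_idx)] <- length(.element_list) + 1L
  el_oh <- matrix(0, n, length(.element_list) + 1L)
  el_oh[cbind(seq_len(n), el_idx)] <- 1
  dg <- pmin(degree, .max_degree)
  dg_oh <- matrix(0, n, .max_degree + 1L)
  dg_oh[cbind(seq_len(n), dg + 1L)] <- 1

  feats <- cbind(el_oh, dg_oh, charge, aromatic)
  colnames(feats) <- NULL
  structure(
    list(node_features = feats, edges = edges, n_atoms = n, smiles = smiles),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$smiles, ": ", x$n_atoms, " atoms, ",
      nrow(x$edges), " bonds\n", sep = "")
  invisible(x)
}

# Symmetric-normalized adjacency with self-connections, D^-1/2 (A+I) D^-1/2.
graph_adjacency_norm <- function(graph) {
  n <- graph$n_atoms
  A <- diag(n)
  if (nrow(graph$edges) > 0L) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  dinv <- 1 / sqrt(rowSums(A))
  A * (dinv %o% dinv)
}

# ---- tables ----------------------------------------------------------------

is_fasta_path <- function(path) {
  grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)
}

read_table_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read the three DTI input tables
#'
#' Reads a protein table (FASTA or delimited with columns `id`, `sequence`),
#' a drug table (`id`, `smiles`) and an interaction table (`drug_id`,
#' `protein_id`, `label` and optionally `affinity`). All id references are
#' validated; exact duplicate interaction rows are dropped, and duplicate
#' (drug, protein) pairs with conflicting labels are an error.
#'
#' @param protein_path,drug_path,interaction_path File paths.
#' @return A list with tibbles `proteins`, `drugs`, `interactions`.
#' @export
read_dti_tables <- function(protein_path, drug_path, interaction_path) {
  for (p in c(protein_path, drug_path, interaction_path)) {
    if (!file.exists(p)) abort(paste0("missing file: ", p))
  }
  proteins <- if (is_fasta_path(protein_path)) {
    ss <- Biostrings::readAAStringSet(protein_path)
    tibble(id = sub("\\s.*$", "", names(ss)), sequence = as.character(ss))
  } else {
    df <- read_table_auto(protein_path)
    stopifnot(all(c("id", "sequence") %in% names(df)))
    tibble(id = as.character(df$id), sequence = as.character(df$sequence))
  }
  proteins$sequence <- toupper(proteins$sequence)
  if (any(!nzchar(proteins$sequence))) abort("empty protein sequence in table")

  drugs <- read_table_auto(drug_path)
  stopifnot(all(c("id", "smiles") %in% names(drugs)))
  drugs <- tibble(id = as.character(drugs$id), smiles = as.character(drugs$smiles))

  inter <- read_table_auto(interaction_path)
  stopifnot(all(c("drug_id", "protein_id", "label") %in% names(inter)))
  inter <- tibble(
    drug_id = as.character(inter$drug_id),
    protein_id = as.character(inter$protein_id),
    label = as.integer(inter$label),
    affinity = if ("affinity" %in% names(inter)) as.numeric(inter$affinity) else NA_real_
  )
  validate_interactions(proteins, drugs, inter)
}

validate_interactions <- function(proteins, drugs, interactions) {
  bad_p <- setdiff(interactions$protein_id, proteins$id)
  if (length(bad_p)) abort(paste0("unresolvable protein id: ", bad_p[1L]))
  bad_d <- setdiff(interactions$drug_id, drugs$id)
  if (length(bad_d)) abort(paste0("unresolvable drug id: ", bad_d[1L]))
  if (!all(interactions$label %in% c(0L, 1L))) abort("labels must be 0 or 1")
  interactions <- dplyr::distinct(interactions)
  key <- paste(interactions$drug_id, interactions$protein_id, sep = "\r")
  conf <- unique(key[duplicated(key)])
  if (length(conf)) {
    pair <- strsplit(conf[1L], "\r", fixed = TRUE)[[1L]]
    abort(paste0("conflicting duplicate labels for pair (", pair[1L], ", ",
                 pair[2L], ")"))
  }
  list(proteins = proteins, drugs = drugs, interactions = interactions)
}

#' Write the DTI tables
#'
#' Writes proteins as FASTA (or TSV), drugs and interactions as TSV, using the
#' same schema [read_dti_tables()] reads.
#'
#' @param data A list with `proteins`, `drugs`, `interactions` tibbles.
#' @param dir Output directory (created if needed).
#' @param protein_format `"fasta"` or `"tsv"`.
#' @return Invisibly, the named vector of written paths.
#' @export
write_dti_tables <- function(data, dir, protein_format = c("fasta", "tsv")) {
  protein_format <- match.arg(protein_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (protein_format == "fasta") {
    ppath <- file.path(dir, "proteins.fasta")
    writeLines(
      as.vector(rbind(paste0(">", data$proteins$id), data$proteins$sequence)),
      ppath
    )
  } else {
    ppath <- file.path(dir, "proteins.tsv")
    readr::write_tsv(data$proteins, ppath, progress = FALSE)
  }
  dpath <- file.path(dir, "drugs.tsv")
  readr::write_tsv(data$drugs, dpath, progress = FALSE)
  ipath <- file.path(dir, "interactions.tsv")
  inter <- data$interactions
  if (all(is.na(inter$affinity))) inter$affinity <- NULL
  readr::write_tsv(inter, ipath, progress = FALSE)
  invisible(c(proteins = ppath, drugs = dpath, interactions = ipath))
}

# ---- protein clustering ----------------------------------------------------

# Normalized k-mer composition matrix over the union of observed k-mers.
kmer_composition <- function(sequences, k = 3L) {
  stopifnot(k >= 1L)
  km <- lapply(sequences, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  })
  vocab <- sort(unique(unlist(km)))
  X <- matrix(0, length(sequences), length(vocab))
  for (i in seq_along(km)) {
    tb <- table(factor(km[[i]], levels = vocab))
    X[i, ] <- as.numeric(tb)
  }
  rs <- rowSums(X)
  rs[rs == 0] <- 1
  X / rs
}

#' Cluster proteins by k-mer composition
#'
#' Represents each protein by its normalized k-mer composition and partitions
#' the set with k-means (fixed seed, multiple restarts). Used both for the
#' source/target domain split and for grouping episodes by protein category.
#'
#' @param proteins Tibble with `id` and `sequence` columns.
#' @param n_clusters Number of clusters (must not exceed the number of
#'   distinct sequences).
#' @param k k-mer length (default 3).
#' @param seed Integer seed; the result is deterministic given
#'   `(proteins, n_clusters, k, seed)`.
#' @return A tibble `protein_id`, `cluster_id` (ids `0..n_clusters-1`), with
#'   attributes `n_clusters` and `feature_kind`.
#' @export
cluster_proteins <- function(proteins, n_clusters, k = 3L, seed = 1L) {
  stopifnot(n_clusters >= 1L)
  n_distinct <- length(unique(proteins$sequence))
  if (n_clusters > n_distinct) {
    abort("n_clusters exceeds the number of distinct proteins")
  }
  if (n_clusters == 1L) {
    cl <- rep(0L, nrow(proteins))
  } else {
    X <- kmer_composition(proteins$sequence, k = k)
    km <- withr::with_seed(seed,
      stats::kmeans(X, centers = n_clusters, nstart = 10L, iter.max = 100L)
    )
    cl <- as.integer(km$cluster) - 1L
  }
  out <- tibble(protein_id = proteins$id, cluster_id = cl)
  attr(out, "n_clusters") <- as.integer(n_clusters)
  attr(out, "feature_kind") <- "kmer_composition"
  out
}

#' Split protein clusters into source and target domains
#'
#' The split is at the cluster level: whole clusters (hence all their
#' proteins) go to one side, so no protein can appear in both domains.
#' The target side receives `max(1, round(n_clusters * target_fraction))`
#' clusters.
#'
#' @param assignment A cluster assignment from [cluster_proteins()].
#' @param target_fraction Fraction of clusters held out as target domain.
#' @param seed Integer seed.
#' @return A list with integer vectors `source` and `target` of cluster ids.
#' @export
split_domains <- function(assignment, target_fraction, seed = 1L) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  ids <- sort(unique(assignment$cluster_id))
  n <- length(ids)
  n_t <- max(1L, round(n * target_fraction))
  if (n_t >= n) abort("target_fraction leaves an empty source side")
  target <- withr::with_seed(seed, sort(sample(ids, n_t)))
  list(source = setdiff(ids, target), target = target)
}

#' Partition interaction rows by domain
#'
#' @param interactions Interaction tibble.
#' @param assignment Cluster assignment tibble.
#' @param split A domain split from [split_domains()].
#' @return List of tibbles `source` and `target`.
#' @export
split_interactions <- function(interactions, assignment, split) {
  cl <- assignment$cluster_id[match(interactions$protein_id, assignment$protein_id)]
  list(
    source = interactions[cl %in% split$source, , drop = FALSE],
    target = interactions[cl %in% split$target, , drop = FALSE]
  )
}

#' Precompute tokens and molecular graphs for a dataset
#'
#' @param data List with `proteins` and `drugs` tibbles.
#' @param l_max Maximum protein length kept (N-terminal prefix).
#' @return A `dti_features` list holding per-id token vectors and graphs.
#' @export
featurize_dataset <- function(data, l_max = 1200L) {
  tokens <- lapply(data$proteins$sequence, function(s) {
    tk <- tokenize_protein(s, l_max = l_max, pad = FALSE)
    tk$tokens
  })
  names(tokens) <- data$proteins$id
  graphs <- lapply(data$drugs$smiles, smiles_to_graph)
  names(graphs) <- data$drugs$id
  for (g in graphs) {
    if (g$n_atoms < 1L) abort("drug with empty graph")
  }
  structure(list(tokens = tokens, graphs = graphs,
                 adj = lapply(graphs, graph_adjacency_norm)),
            class = "dti_features")
}
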