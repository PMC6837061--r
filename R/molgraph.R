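#' Atom feature scheme
#'
#' Defines the fixed-length atom/bond featurization used throughout the
#' package. Atom features are the concatenation of: a one-hot element
#' indicator over `elements` plus a trailing "other" slot, a one-hot heavy
#' degree (0--5), a one-hot attached-hydrogen count (0--4), a one-hot
#' implicit valence (0--5) and an aromaticity flag. Bond features are a
#' one-hot bond order (single/double/triple/aromatic), a conjugation flag
#' and an in-ring flag.
#'
#' @param elements character vector of element symbols given dedicated
#'   one-hot slots; anything else maps to the shared "other" slot.
#' @return an object of class `atom_feature_spec` with fields `elements`,
#'   `n_atom_features` and `n_bond_features`.
#' @export
atom_feature_spec <- function(elements = c("C", "N", "O", "S", "F",
                                           "Cl", "Br", "I", "P")) {
  stopifnot(is.character(elements), length(elements) >= 1)
  spec <- list(
    elements = elements,
    n_atom_features = (length(elements) + 1L) + 6L + 5L + 6L + 1L,
    n_bond_features = 4L + 1L + 1L
  )
  class(spec) <- "atom_feature_spec"
  spec
}

# standard heavy-atom valences used to infer implicit hydrogen counts
.default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, B = 3, Si = 4)

.one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  k <- match(value, levels)
  if (!is.na(k)) v[k] <- 1
  v
}

# Convert SMILES to MOL2 text via Open Babel and split into raw
# per-molecule records. Titles are set to the input index so dropped
# (invalid) entries can be identified; a severe parse error can abort the
# Open Babel stream, so molecules missing after the batch pass are retried
# one at a time. Returns a list of length(smiles); NULL where parsing
# failed.
.ob_parse <- function(smiles) {
  stopifnot(is.character(smiles))
  convert <- function(strings, ids) {
    src <- paste0(paste(strings, ids), "\n", collapse = "")
    txt <- tryCatch(
      ChemmineOB::convertFormat("SMI", "MOL2", source = src),
      error = function(e) ""
    )
    if (!nzchar(txt)) return(list())
    blocks <- strsplit(txt, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
    Filter(Negate(is.null), lapply(blocks[nzchar(trimws(blocks))],
                                   .parse_mol2_block))
  }
  out <- vector("list", length(smiles))
  fill <- function(recs) {
    for (rec in recs) {
      idx <- suppressWarnings(as.integer(rec$title))
      if (!is.na(idx) && idx >= 1 && idx <= length(smiles))
        out[[idx]] <<- rec
    }
  }
  fill(convert(smiles, seq_along(smiles)))
  missing <- which(vapply(out, is.null, logical(1)))
  if (length(missing) && length(missing) < length(smiles)) {
    # a mid-stream failure may have truncated the batch: retry singly
    for (k in missing) fill(convert(smiles[k], k))
  }
  out
}

# Parse one MOL2 molecule block (text after the MOLECULE tag) into element
# symbols, a bond table and formal charges.
.parse_mol2_block <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) return(NULL)
  title <- trimws(lines[1])
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  n_atoms <- counts[1]
  n_bonds <- if (length(counts) >= 2) counts[2] else 0L
  if (is.na(n_atoms) || n_atoms < 1) return(NULL)

  sec <- function(tag) {
    i <- match(paste0("@<TRIPOS>", tag), trimws(lines))
    if (is.na(i)) return(character(0))
    j <- i + 1
    while (j <= length(lines) && !startsWith(trimws(lines[j]), "@<TRIPOS>"))
      j <- j + 1
    if (j <= i + 1) return(character(0))
    lines[(i + 1):(j - 1)]
  }

  atom_lines <- sec("ATOM")
  if (length(atom_lines) < n_atoms) return(NULL)
  atom_fields <- lapply(atom_lines[seq_len(n_atoms)],
                        function(l) strsplit(trimws(l), "\\s+")[[1]])
  sybyl <- vapply(atom_fields, function(f) f[6], character(1))
  element <- sub("\\..*$", "", sybyl)

  bonds <- NULL
  if (n_bonds > 0) {
    bond_lines <- sec("BOND")
    bf <- lapply(bond_lines[seq_len(n_bonds)],
                 function(l) strsplit(trimws(l), "\\s+")[[1]])
    bonds <- data.frame(
      i = vapply(bf, function(f) as.integer(f[2]), integer(1)),
      j = vapply(bf, function(f) as.integer(f[3]), integer(1)),
      type = vapply(bf, function(f) f[4], character(1)),
      stringsAsFactors = FALSE
    )
  }

  charge <- integer(n_atoms)
  attr_lines <- sec("UNITY_ATOM_ATTR")
  k <- 1
  while (k < length(attr_lines)) {
    head_f <- strsplit(trimws(attr_lines[k]), "\\s+")[[1]]
    aid <- as.integer(head_f[1]); nat <- as.integer(head_f[2])
    for (a in seq_len(nat)) {
      f <- strsplit(trimws(attr_lines[k + a]), "\\s+")[[1]]
      if (identical(f[1], "charge")) charge[aid] <- as.integer(f[2])
    }
    k <- k + nat + 1
  }

  list(title = title, element = element, sybyl = sybyl,
       bonds = bonds, charge = charge)
}

# numeric bond order used for valence accounting; aromatic counts 1.5
.bond_order_num <- function(type) {
  switch(type, "1" = 1, "2" = 2, "3" = 3, "ar" = 1.5, "am" = 1, "du" = 1, 1)
}

#' Parse a SMILES string into an attributed molecular graph
#'
#' Produces the heavy-atom graph (hydrogens are implicit and enter the atom
#' features as counts). Atom order is the parser's order and is
#' deterministic for a given input string. For disconnected inputs (salts,
#' mixtures) only the largest fragment is kept.
#'
#' @param smiles a single SMILES string.
#' @param spec an [atom_feature_spec()].
#' @return an object of class `mol_graph`: atom feature matrix
#'   (`n_atoms x n_atom_features`), bond table with per-bond feature
#'   vectors, neighbor index list and per-atom degrees.
#' @export
parse_smiles <- function(smiles, spec = atom_feature_spec()) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(trimws(smiles)))
    stop("parse_smiles() expects one non-empty SMILES string")
  raw <- .ob_parse(smiles)[[1]]
  if (is.null(raw))
    stop(sprintf("could not parse SMILES string: '%s'", smiles))
  g <- .graph_from_raw(raw, spec, smiles)
  if (is.null(g))
    stop(sprintf("could not parse SMILES string: '%s'", smiles))
  g
}

# Build a mol_graph from a raw MOL2 record. Returns NULL on structural
# failure (used by the batch path); atom degree > 5 raises an error.
.graph_from_raw <- function(raw, spec, smiles) {
  n <- length(raw$element)
  bonds <- raw$bonds

  # adjacency bookkeeping
  neighbors <- rep(list(integer(0)), n)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      neighbors[[i]] <- c(neighbors[[i]], j)
      neighbors[[j]] <- c(neighbors[[j]], i)
    }
  }

  # largest connected fragment
  comp <- .components(n, neighbors)
  if (max(comp) > 1) {
    sizes <- tabulate(comp)
    keep_c <- which.max(sizes)
    keep <- which(comp == keep_c)
    remap <- match(seq_len(n), keep)
    raw$element <- raw$element[keep]
    raw$sybyl <- raw$sybyl[keep]
    raw$charge <- raw$charge[keep]
    if (!is.null(bonds)) {
      bonds <- bonds[bonds$i %in% keep & bonds$j %in% keep, , drop = FALSE]
      bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    }
    n <- length(keep)
    neighbors <- rep(list(integer(0)), n)
    if (!is.null(bonds) && nrow(bonds) > 0) {
      for (b in seq_len(nrow(bonds))) {
        i <- bonds$i[b]; j <- bonds$j[b]
        neighbors[[i]] <- c(neighbors[[i]], j)
        neighbors[[j]] <- c(neighbors[[j]], i)
      }
    }
  }

  degree <- lengths(neighbors)
  if (any(degree > 5))
    stop(sprintf(
      "atom with heavy degree %d in '%s': degrees above 5 are not supported",
      max(degree), smiles))

  aromatic_atom <- grepl("\\.ar$", raw$sybyl)
  n_bonds <- if (is.null(bonds)) 0L else nrow(bonds)

  # valence accounting -> implicit hydrogens
  order_sum <- numeric(n)
  has_multiple <- logical(n)
  if (n_bonds > 0) {
    ord <- vapply(bonds$type, .bond_order_num, numeric(1))
    for (b in seq_len(n_bonds)) {
      order_sum[bonds$i[b]] <- order_sum[bonds$i[b]] + ord[b]
      order_sum[bonds$j[b]] <- order_sum[bonds$j[b]] + ord[b]
      if (ord[b] > 1) {
        has_multiple[bonds$i[b]] <- TRUE
        has_multiple[bonds$j[b]] <- TRUE
      }
    }
  }
  val <- .default_valence[raw$element]
  val[is.na(val)] <- 4
  val <- val + raw$charge   # N+ -> 4, O- -> 1, etc.
  h_count <- pmax(0, round(val - ceiling(order_sum)))
  h_count <- pmin(h_count, 4)
  implicit_valence <- pmin(h_count, 5)

  # ring bonds: an edge is in a ring iff it is not a bridge
  ring_bond <- logical(n_bonds)
  if (n_bonds > 0) {
    ig <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j),
                                      directed = FALSE)
    br <- igraph::bridges(ig)
    ring_bond <- !(seq_len(n_bonds) %in% as.integer(br))
  }

  # atom features
  elem_levels <- c(spec$elements, ".other")
  elem_key <- ifelse(raw$element %in% spec$elements, raw$element, ".other")
  X <- matrix(0, nrow = n, ncol = spec$n_atom_features)
  for (v in seq_len(n)) {
    X[v, ] <- c(.one_hot(elem_key[v], elem_levels),
                .one_hot(degree[v], 0:5),
                .one_hot(h_count[v], 0:4),
                .one_hot(implicit_valence[v], 0:5),
                as.numeric(aromatic_atom[v]))
  }

  # bond features (symmetric by construction: one row per undirected bond)
  B <- matrix(0, nrow = n_bonds, ncol = spec$n_bond_features)
  if (n_bonds > 0) {
    for (b in seq_len(n_bonds)) {
      type <- bonds$type[b]
      conj <- identical(type, "ar") ||
        (has_multiple[bonds$i[b]] && has_multiple[bonds$j[b]])
      B[b, ] <- c(.one_hot(type, c("1", "2", "3", "ar")),
                  as.numeric(conj),
                  as.numeric(ring_bond[b]))
    }
    # am/du orders fold into the single-bond slot
    unk <- !(bonds$type %in% c("1", "2", "3", "ar"))
    if (any(unk)) B[unk, 1] <- 1
  }

  structure(list(
    n_atoms = n,
    elements = raw$element,
    atom_features = X,
    bonds = if (n_bonds > 0) bonds[, c("i", "j")] else
      data.frame(i = integer(0), j = integer(0)),
    bond_features = B,
    neighbors = neighbors,
    degree = as.integer(degree),
    aromatic = aromatic_atom,
    smiles = smiles,
    spec = spec
  ), class = "mol_graph")
}

.components <- function(n, neighbors) {
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in neighbors[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("mol_graph: %d atoms, %d bonds (%s)\n",
              x$n_atoms, nrow(x$bonds), x$smiles))
  invisible(x)
}

#' Parse a vector of SMILES strings
#'
#' Batch counterpart of [parse_smiles()]. Unparseable entries yield `NULL`
#' elements (with a single summary warning) rather than an error, so dirty
#' datasets survive ingestion.
#'
#' @param smiles character vector.
#' @param spec an [atom_feature_spec()].
#' @return list of `mol_graph` or `NULL`, same length as `smiles`.
#' @export
parse_smiles_batch <- function(smiles, spec = atom_feature_spec()) {
  raws <- .ob_parse(smiles)
  out <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    if (is.null(raws[[k]])) next
    out[[k]] <- tryCatch(.graph_from_raw(raws[[k]], spec, smiles[k]),
                         error = function(e) NULL)
  }
  n_bad <- sum(vapply(out, is.null, logical(1)))
  if (n_bad > 0)
    warning(sprintf("%d of %d SMILES could not be parsed and were dropped",
                    n_bad, length(smiles)))
  out
}

#' Read a molecular dataset from CSV
#'
#' Reads a CSV with a SMILES column and (optionally) a numeric property
#' column. Rows whose SMILES cannot be parsed are dropped with a warning;
#' rows with a missing target are kept as unlabelled records for the
#' semi-supervised stage.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param smiles_col,target_col column names; set `target_col = NULL` for a
#'   structures-only file.
#' @param spec an [atom_feature_spec()].
#' @return a `mol_dataset`: list with `graphs`, `smiles`, `y` (NA where
#'   unlabelled) and `n_dropped`.
#' @export
read_dataset <- function(path, smiles_col = "smiles", target_col = "y",
                         spec = atom_feature_spec()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!smiles_col %in% names(df))
    stop(sprintf("column '%s' not present in %s", smiles_col, path))
  smiles <- as.character(df[[smiles_col]])
  y <- rep(NA_real_, length(smiles))
  if (!is.null(target_col)) {
    if (target_col %in% names(df)) {
      y <- suppressWarnings(as.numeric(df[[target_col]]))
    } else if (!missing(target_col)) {
      stop(sprintf("column '%s' not present in %s", target_col, path))
    }
    # default target_col absent from the file: structures-only CSV,
    # all rows enter unlabelled
  }
  graphs <- parse_smiles_batch(smiles, spec)
  ok <- !vapply(graphs, is.null, logical(1))
  structure(list(
    graphs = graphs[ok],
    smiles = smiles[ok],
    y = y[ok],
    n_dropped = sum(!ok),
    spec = spec
  ), class = "mol_dataset")
}

#' Assemble a mol_dataset from in-memory SMILES
#'
#' @param smiles character vector; `y` optional numeric labels (NA allowed).
#' @inheritParams read_dataset
#' @export
mol_dataset <- function(smiles, y = rep(NA_real_, length(smiles)),
                        spec = atom_feature_spec()) {
  stopifnot(length(smiles) == length(y))
  graphs <- parse_smiles_batch(smiles, spec)
  ok <- !vapply(graphs, is.null, logical(1))
  structure(list(graphs = graphs[ok], smiles = smiles[ok],
                 y = as.numeric(y)[ok], n_dropped = sum(!ok), spec = spec),
            class = "mol_dataset")
}

#' @export
print.mol_dataset <- function(x, ...) {
  cat(sprintf("mol_dataset: %d molecules (%d labelled, %d dropped at parse)\n",
              length(x$graphs), sum(!is.na(x$y)), x$n_dropped))
  invisible(x)
}

#' Interpretable whole-molecule graph statistics
#'
#' Heavy-atom count, aromatic-ring count (cycle rank of the aromatic-atom
#' subgraph) and heteroatom (non-carbon) count. These are the covariates of
#' the synthetic ground-truth property.
#'
#' @param graph a `mol_graph`.
#' @return named numeric vector `c(heavy, aromatic_rings, hetero)`.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  n_arom_ring <- 0
  if (nrow(graph$bonds) > 0) {
    arom_bond <- graph$bond_features[, 4] == 1
    if (any(arom_bond)) {
      verts <- unique(c(graph$bonds$i[arom_bond], graph$bonds$j[arom_bond]))
      sub_n <- length(verts)
      sub_e <- sum(arom_bond)
      ig <- igraph::graph_from_edgelist(
        cbind(match(graph$bonds$i[arom_bond], verts),
              match(graph$bonds$j[arom_bond], verts)), directed = FALSE)
      n_comp <- igraph::count_components(ig)
      n_arom_ring <- sub_e - sub_n + n_comp
    }
  }
  c(heavy = graph$n_atoms,
    aromatic_rings = n_arom_ring,
    hetero = sum(graph$elements != "C"))
}

#' Dump a featurized graph as JSON (debugging aid)
#'
#' @param graph a `mol_graph`; `path` optional output file.
#' @return JSON string, invisibly when written to a file.
#' @export
graph_to_json <- function(graph, path = NULL) {
  obj <- list(smiles = graph$smiles, n_atoms = graph$n_atoms,
              elements = graph$elements, degree = graph$degree,
              atom_features = graph$atom_features,
              bonds = graph$bonds, bond_features = graph$bond_features)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
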