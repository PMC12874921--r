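# Input parsing and featurization: SMILES -> molecular graphs, interaction
# tables, STRING-style PPI edge lists, protein tokenization.

#' Atom feature configuration
#'
#' Defines the layout of the per-atom feature vector used by the molecular
#' graph encoder: a one-hot atom type over 44 common elements plus an "other"
#' slot (45), one-hot heavy-atom degree 0--10 (11), one-hot total hydrogen
#' count 0--10 (11), one-hot implicit valence 0--10 (11), and an aromaticity
#' flag (1), for a total width of 79.
#'
#' @param elements Character vector of element symbols receiving a dedicated
#'   one-hot slot; anything else falls into the shared "other" slot.
#' @return A list with the element vocabulary, category caps and total
#'   feature width (`$width`, always 79 for the default configuration).
#' @export
atom_feature_config <- function(elements = c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "W")) {
  stopifnot(is.character(elements), !anyDuplicated(elements))
  cfg <- list(
    elements = elements,
    max_degree = 10L,
    max_hydrogens = 10L,
    max_valence = 10L
  )
  cfg$width <- (length(elements) + 1L) +
    (cfg$max_degree + 1L) + (cfg$max_hydrogens + 1L) + (cfg$max_valence + 1L) + 1L
  class(cfg) <- "atom_feature_config"
  cfg
}

stop_invalid_smiles <- function(smiles) {
  cnd <- structure(
    class = c("dtifuse_invalid_smiles", "error", "condition"),
    list(message = sprintf("invalid SMILES string: '%s'", smiles),
         call = sys.call(-1), smiles = smiles)
  )
  stop(cnd)
}

# Convert a SMILES string to a parsed MOL2 structure via OpenBabel.
# Returns NULL when OpenBabel cannot parse the string.
ob_mol2 <- function(smiles, add_h = FALSE) {
  txt <- ""
  # capture OpenBabel's console noise for unparseable strings
  utils::capture.output(type = "message", {
    txt <- tryCatch(
      if (add_h) {
        ChemmineOB::convertFormat("SMI", "MOL2", source = smiles,
                                  options = data.frame(names = "h", args = ""))
      } else {
        ChemmineOB::convertFormat("SMI", "MOL2", source = smiles)
      },
      error = function(e) ""
    )
  })
  if (!is.character(txt) || !nzchar(trimws(txt))) return(NULL)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  # drop an empty BOND section (single-atom molecules) that trips the reader
  bh <- which(trimws(lines) == "@<TRIPOS>BOND")
  if (length(bh) == 1L) {
    rest <- trimws(lines[seq_along(lines) > bh])
    if (!any(nzchar(rest) & !startsWith(rest, "@"))) lines <- lines[-bh]
  }
  tf <- tempfile(fileext = ".mol2")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  mol <- tryCatch(suppressWarnings(bio3d::read.mol2(tf)), error = function(e) NULL)
  if (is.null(mol) || is.null(mol$atom) || nrow(mol$atom) == 0L) return(NULL)
  mol
}

one_hot <- function(index, n) {
  v <- numeric(n)
  v[index] <- 1
  v
}

#' Parse a SMILES string into a molecular graph
#'
#' Atoms become nodes carrying a 79-dimensional feature vector (see
#' [atom_feature_config()]); bonds become undirected edges. Hydrogens are
#' implicit: they contribute to the hydrogen-count feature but are not graph
#' nodes. Parsing is delegated to OpenBabel (via \pkg{ChemmineOB}); the SYBYL
#' atom types of the resulting MOL2 record supply the aromaticity flags.
#'
#' @param smiles A single SMILES string.
#' @param feature_config An [atom_feature_config()].
#' @return An object of class `molecular_graph`: a list with
#'   `atom_features` (n_atoms x 79 matrix), `bonds` (m x 2 integer matrix of
#'   1-based atom indices, each row `i < j`), and `source_smiles`.
#' @section Errors: an unparseable SMILES raises a condition of class
#'   `dtifuse_invalid_smiles` carrying the offending string, so dataset
#'   loaders can drop the record and count it.
#' @examples
#' g <- parse_smiles_to_graph("CC")
#' nrow(g$atom_features)  # 2 atoms
#' g$bonds                # one bond between atoms 1 and 2
#' @export
parse_smiles_to_graph <- function(smiles, feature_config = atom_feature_config()) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop_invalid_smiles(if (length(smiles) == 1L) as.character(smiles) else "")
  }
  heavy <- ob_mol2(smiles, add_h = FALSE)
  if (is.null(heavy)) stop_invalid_smiles(smiles)
  n <- nrow(heavy$atom)
  element <- sub("\\..*$", "", heavy$atom$elety)
  aromatic <- as.numeric(grepl("\\.ar$", heavy$atom$elety))

  bonds <- matrix(integer(0), ncol = 2)
  if (!is.null(heavy$bond) && nrow(heavy$bond) > 0L) {
    b <- cbind(as.integer(heavy$bond$origin), as.integer(heavy$bond$target))
    b <- t(apply(b, 1L, sort))
    b <- unique(b[b[, 1L] != b[, 2L], , drop = FALSE])
    bonds <- b
  }
  if (nrow(bonds) > 0L && max(bonds) > n) {
    stop_invalid_smiles(smiles)  # inconsistent bond table
  }

  degree <- tabulate(c(bonds[, 1L], bonds[, 2L]), nbins = n)

  # Hydrogen counts from a second conversion with explicit hydrogens;
  # OpenBabel appends hydrogens after the heavy atoms, preserving their order.
  h_count <- integer(n)
  withh <- ob_mol2(smiles, add_h = TRUE)
  if (!is.null(withh) && !is.null(withh$bond) && nrow(withh$bond) > 0L) {
    elem_h <- sub("\\..*$", "", withh$atom$elety)
    is_h <- elem_h == "H"
    # hydrogens already explicit in the input occupy heavy-atom positions;
    # count any H neighbor of each of the first n atoms
    o <- as.integer(withh$bond$origin)
    t2 <- as.integer(withh$bond$target)
    for (r in seq_along(o)) {
      if (o[r] <= n && t2[r] <= length(is_h) && is_h[t2[r]]) {
        h_count[o[r]] <- h_count[o[r]] + 1L
      }
      if (t2[r] <= n && o[r] <= length(is_h) && is_h[o[r]]) {
        h_count[t2[r]] <- h_count[t2[r]] + 1L
      }
    }
  }
  # Implicit valence: the implicit-hydrogen capacity of each atom. For SMILES
  # input (hydrogens implicit) this equals the hydrogen count derived above.
  implicit_valence <- h_count

  cfg <- feature_config
  n_el <- length(cfg$elements)
  feats <- matrix(0, nrow = n, ncol = cfg$width)
  for (i in seq_len(n)) {
    slot <- match(element[i], cfg$elements)
    if (is.na(slot)) slot <- n_el + 1L
    off <- 0L
    feats[i, off + slot] <- 1
    off <- n_el + 1L
    feats[i, off + min(degree[i], cfg$max_degree) + 1L] <- 1
    off <- off + cfg$max_degree + 1L
    feats[i, off + min(h_count[i], cfg$max_hydrogens) + 1L] <- 1
    off <- off + cfg$max_hydrogens + 1L
    feats[i, off + min(implicit_valence[i], cfg$max_valence) + 1L] <- 1
    feats[i, cfg$width] <- aromatic[i]
  }

  structure(
    list(atom_features = feats,
         bonds = bonds,
         source_smiles = smiles),
    class = "molecular_graph"
  )
}

#' Binarize a dissociation constant into an interaction label
#'
#' Pairs with `Kd` strictly below the threshold (30 nM by convention for
#' DAVIS-style affinity tables) are positives; everything else, including the
#' boundary value, is negative.
#'
#' @param kd Numeric vector of non-negative dissociation constants (nM).
#' @param threshold Positivity threshold; strict `<` comparison.
#' @return Integer vector of labels in `{0, 1}`.
#' @export
binarize_affinity <- function(kd, threshold = 30) {
  if (!is.numeric(kd) || anyNA(kd)) stop("kd must be numeric and non-missing")
  if (any(kd < 0)) stop("kd must be non-negative")
  as.integer(kd < threshold)
}

#' Load a drug-target interaction table
#'
#' Reads a delimited text file with drug identifiers, SMILES, protein
#' identifiers, amino-acid sequences, and either a binary label column or a
#' Kd affinity column (binarized via [binarize_affinity()]). Rows whose
#' SMILES cannot be parsed into a molecular graph are dropped and counted.
#' Duplicate (drug, protein) pairs with equal labels collapse to one record;
#' conflicting duplicate labels are a hard error.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named list mapping roles to column names: `drug_id`,
#'   `smiles`, `protein_id`, `sequence`, and one of `label` or `kd`.
#' @param sep Field separator (default tab).
#' @param kd_threshold Threshold passed to [binarize_affinity()].
#' @return A list with `dataset` (class `interaction_dataset`: `records`
#'   data frame with columns drug_id/protein_id/label, plus named character
#'   vectors `drug_table` and `protein_table`) and `report` (rows read, kept,
#'   dropped for invalid SMILES, duplicates collapsed).
#' @export
load_interaction_table <- function(path,
                                   schema = list(drug_id = "drug_id",
                                                 smiles = "smiles",
                                                 protein_id = "protein_id",
                                                 sequence = "sequence",
                                                 label = "label"),
                                   sep = "\t",
                                   kd_threshold = 30) {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) stop("interaction table is empty: ", path)
  need <- c("drug_id", "smiles", "protein_id", "sequence")
  for (role in need) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(df)) {
      stop("missing required column for role '", role, "'")
    }
  }
  has_label <- !is.null(schema$label) && schema$label %in% names(df)
  has_kd <- !is.null(schema$kd) && schema$kd %in% names(df)
  if (!has_label && !has_kd) stop("table needs a label column or a Kd column")

  drug_id <- as.character(df[[schema$drug_id]])
  smiles <- as.character(df[[schema$smiles]])
  protein_id <- as.character(df[[schema$protein_id]])
  sequence <- toupper(as.character(df[[schema$sequence]]))
  label <- if (has_label) {
    lb <- df[[schema$label]]
    if (!all(lb %in% c(0, 1))) stop("label column must be binary 0/1")
    as.integer(lb)
  } else {
    binarize_affinity(as.numeric(df[[schema$kd]]), threshold = kd_threshold)
  }

  # Drop drugs with invalid SMILES (all their rows)
  udrug <- !duplicated(drug_id)
  valid_drug <- vapply(which(udrug), function(i) {
    tryCatch({ parse_smiles_to_graph(smiles[i]); TRUE },
             dtifuse_invalid_smiles = function(e) FALSE)
  }, logical(1))
  names(valid_drug) <- drug_id[udrug]
  keep <- valid_drug[drug_id]
  dropped <- sum(!keep)

  drug_id <- drug_id[keep]; smiles <- smiles[keep]
  protein_id <- protein_id[keep]; sequence <- sequence[keep]
  label <- label[keep]

  if (length(drug_id) == 0L) stop("no valid records after SMILES filtering")

  pair <- paste(drug_id, protein_id, sep = "\r")
  dup <- duplicated(pair)
  if (any(dup)) {
    agg <- tapply(label, pair, function(x) length(unique(x)))
    if (any(agg > 1L)) {
      bad <- names(agg)[agg > 1L][1L]
      stop("conflicting labels for duplicate pair: ",
           gsub("\r", " / ", bad))
    }
  }
  n_dup <- sum(dup)
  drug_tab <- smiles[!duplicated(drug_id)]
  names(drug_tab) <- drug_id[!duplicated(drug_id)]
  prot_tab <- sequence[!duplicated(protein_id)]
  names(prot_tab) <- protein_id[!duplicated(protein_id)]

  records <- data.frame(drug_id = drug_id[!dup],
                        protein_id = protein_id[!dup],
                        label = label[!dup],
                        stringsAsFactors = FALSE)
  dataset <- structure(
    list(records = records, drug_table = drug_tab, protein_table = prot_tab),
    class = "interaction_dataset"
  )
  list(dataset = dataset,
       report = list(rows_read = length(keep), rows_kept = nrow(records),
                     dropped_invalid_smiles = dropped,
                     duplicates_collapsed = n_dup))
}

#' Construct an interaction dataset from in-memory tables
#'
#' @param records Data frame with columns `drug_id`, `protein_id`, `label`.
#' @param drug_table Named character vector: drug_id -> SMILES.
#' @param protein_table Named character vector: protein_id -> sequence.
#' @return An `interaction_dataset`.
#' @export
interaction_dataset <- function(records, drug_table, protein_table) {
  stopifnot(all(c("drug_id", "protein_id", "label") %in% names(records)),
            all(records$label %in% c(0L, 1L)),
            all(records$drug_id %in% names(drug_table)),
            all(records$protein_id %in% names(protein_table)))
  pair <- paste(records$drug_id, records$protein_id, sep = "\r")
  if (anyDuplicated(pair)) stop("duplicate (drug, protein) pairs")
  structure(list(records = records,
                 drug_table = drug_table,
                 protein_table = protein_table),
            class = "interaction_dataset")
}

#' Load a STRING-style PPI edge list
#'
#' Expects whitespace- or tab-delimited rows `protein_a protein_b score`.
#' Only edges whose both endpoints belong to `id_universe` (the proteins of
#' the interaction dataset under study) are kept; edges are symmetrized and
#' deduplicated keeping the maximum confidence score.
#'
#' @param path Path to the edge-list file (a header row is detected and
#'   skipped when the third field is non-numeric).
#' @param id_universe Character vector of admissible protein identifiers.
#' @return Data frame with columns `a`, `b` (each row `a < b` lexically) and
#'   `score`. May have zero rows.
#' @export
load_ppi_edges <- function(path, id_universe) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(a = character(0), b = character(0), score = numeric(0)))
  }
  parts <- strsplit(trimws(lines), "[\t ]+")
  a <- character(0); b <- character(0); s <- numeric(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L) {
      warning("malformed PPI row ", i, ": '", lines[i], "'")
      next
    }
    sc <- suppressWarnings(as.numeric(p[3L]))
    if (is.na(sc)) {
      if (i > 1L) warning("malformed PPI row ", i, ": non-numeric score")
      next  # header or bad row
    }
    a <- c(a, p[1L]); b <- c(b, p[2L]); s <- c(s, sc)
  }
  keep <- a %in% id_universe & b %in% id_universe & a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (length(a) == 0L) {
    return(data.frame(a = character(0), b = character(0), score = numeric(0)))
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  score <- tapply(s, key, max)
  ks <- strsplit(names(score), "\r", fixed = TRUE)
  out <- data.frame(a = vapply(ks, `[`, "", 1L),
                    b = vapply(ks, `[`, "", 2L),
                    score = as.numeric(score),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$a, out$b), , drop = FALSE]
}

#' Amino-acid token vocabulary
#'
#' The 20 standard amino acids plus 'X' for unknowns. Token index 0 is
#' reserved for padding; residues map to 1..21.
#' @return Named integer vector of token indices.
#' @export
protein_vocab <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  stats::setNames(seq_along(aa), aa)
}

#' Tokenize a protein sequence
#'
#' Maps residues to integer tokens (see [protein_vocab()]), truncates at
#' `max_len` and right-pads with the reserved index 0. Characters outside the
#' alphabet map to 'X' with a warning (never fatal).
#'
#' @param sequence Amino-acid sequence (single string).
#' @param max_len Maximum token length (default 1024, the protein length cap).
#' @return Integer vector of length `max_len`.
#' @export
tokenize_protein <- function(sequence, max_len = 1024L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence),
            max_len >= 1L)
  vocab <- protein_vocab()
  chars <- strsplit(toupper(sequence), "")[[1L]]
  chars <- chars[seq_len(min(length(chars), max_len))]
  idx <- unname(vocab[chars])
  if (anyNA(idx)) {
    warning("unknown residues mapped to 'X': ",
            paste(unique(chars[is.na(idx)]), collapse = ""))
    idx[is.na(idx)] <- vocab[["X"]]
  }
  c(idx, integer(max_len - length(idx)))
}

#' Write / read the internal dataset cache (JSON lines)
#'
#' Serializes an `interaction_dataset` to a JSON-lines file with a schema
#' version header so cached featurizations are reproducible and versioned.
#' @param dataset An `interaction_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_cache <- function(dataset, path) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(schema_version = 1L,
                                   type = "header"), auto_unbox = TRUE), con)
  for (id in names(dataset$drug_table)) {
    writeLines(jsonlite::toJSON(list(type = "drug", id = id,
                                     smiles = dataset$drug_table[[id]]),
                                auto_unbox = TRUE), con)
  }
  for (id in names(dataset$protein_table)) {
    writeLines(jsonlite::toJSON(list(type = "protein", id = id,
                                     sequence = dataset$protein_table[[id]]),
                                auto_unbox = TRUE), con)
  }
  r <- dataset$records
  for (i in seq_len(nrow(r))) {
    writeLines(jsonlite::toJSON(list(type = "pair", drug_id = r$drug_id[i],
                                     protein_id = r$protein_id[i],
                                     label = r$label[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_dataset_cache
#' @export
read_dataset_cache <- function(path) {
  lines <- readLines(path, warn = FALSE)
  objs <- lapply(lines, jsonlite::fromJSON)
  hdr <- objs[[1L]]
  if (!identical(hdr$type, "header") || hdr$schema_version != 1L) {
    stop("unrecognized dataset cache schema")
  }
  types <- vapply(objs, function(o) o$type, "")
  dt <- objs[types == "drug"]
  pt <- objs[types == "protein"]
  pr <- objs[types == "pair"]
  drug_table <- stats::setNames(vapply(dt, function(o) o$smiles, ""),
                                vapply(dt, function(o) o$id, ""))
  protein_table <- stats::setNames(vapply(pt, function(o) o$sequence, ""),
                                   vapply(pt, function(o) o$id, ""))
  records <- data.frame(
    drug_id = vapply(pr, function(o) o$drug_id, ""),
    protein_id = vapply(pr, function(o) o$protein_id, ""),
    label = vapply(pr, function(o) as.integer(o$label), 1L),
    stringsAsFactors = FALSE
  )
  interaction_dataset(records, drug_table, protein_table)
}
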