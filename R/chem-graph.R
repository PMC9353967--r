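#' Atom featurization configuration
#'
#' Layout of the binary per-atom feature vector: an element one-hot block, a
#' heavy-atom-degree block, a hydrogen-count block, an implicit-valence block
#' and a single aromatic bit, concatenated in that fixed order. With the
#' defaults (43 elements, 10 slots each for degree / hydrogens / implicit
#' valence, 1 aromatic bit) the total length is 74.
#'
#' The default element vocabulary is the 42 elements commonly used by
#' molecular-graph DTA models plus a final catch-all "Unknown" symbol; it is
#' fully configurable, and atoms of elements outside the vocabulary map to
#' the unknown slot with a warning rather than failing. Degree, hydrogen and
#' valence values at or beyond their block size clip into the last slot so
#' that unusual molecules never crash featurization.
#'
#' @param elementVocab ordered character vector of element symbols; must be
#'   unique and contain "Unknown".
#' @param maxDegree,maxNumH,maxImplicitValence number of one-hot slots for
#'   the respective integer descriptors (values 0 .. max-1, larger clipped).
#' @return A named list of class `AtomFeatureConfig`.
#' @examples
#' cfg <- atomFeatureConfig()
#' length(cfg$elementVocab) # 43
#' cfg$featureLength        # 74
#' @export
atomFeatureConfig <- function(elementVocab = defaultElementVocab(),
                              maxDegree = 10L, maxNumH = 10L,
                              maxImplicitValence = 10L) {
  stopIfNot(!anyDuplicated(elementVocab), "elementVocab entries must be unique")
  stopIfNot("Unknown" %in% elementVocab,
            "elementVocab must contain an 'Unknown' catch-all symbol")
  stopIfNot(maxDegree >= 1 && maxNumH >= 1 && maxImplicitValence >= 1,
            "block sizes must be >= 1")
  cfg <- list(elementVocab = as.character(elementVocab),
              maxDegree = as.integer(maxDegree),
              maxNumH = as.integer(maxNumH),
              maxImplicitValence = as.integer(maxImplicitValence),
              featureLength = length(elementVocab) + as.integer(maxDegree) +
                as.integer(maxNumH) + as.integer(maxImplicitValence) + 1L)
  class(cfg) <- c("AtomFeatureConfig", "list")
  cfg
}

#' @rdname atomFeatureConfig
#' @export
defaultElementVocab <- function() {
  c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
    "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
    "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
    "Zr", "Cr", "Pt", "Hg", "Unknown")
}

oneHot <- function(index0, size) {
  v <- numeric(size)
  v[min(index0, size - 1L) + 1L] <- 1 # clip into the last slot
  v
}

#' Featurize one atom
#'
#' Maps an atom descriptor (element symbol, heavy-atom degree, hydrogen
#' count, implicit valence, aromatic flag) to the fixed binary layout of
#' [atomFeatureConfig()].
#'
#' @param descriptor list or data.frame row with fields `element`, `degree`,
#'   `numH`, `implicitValence`, `aromatic`.
#' @param config an [atomFeatureConfig()].
#' @return Numeric 0/1 vector of length `config$featureLength`.
#' @examples
#' f <- featurizeAtom(list(element = "C", degree = 0, numH = 4,
#'                         implicitValence = 4, aromatic = FALSE))
#' sum(f) # 4: element, degree, numH, valence blocks each contribute one 1
#' @export
featurizeAtom <- function(descriptor, config = atomFeatureConfig()) {
  el <- as.character(descriptor$element)
  deg <- as.integer(descriptor$degree)
  nh <- as.integer(descriptor$numH)
  iv <- as.integer(descriptor$implicitValence)
  stopIfNot(deg >= 0 && nh >= 0 && iv >= 0,
            "descriptor fields must be non-negative")
  ei <- match(el, config$elementVocab)
  if (is.na(ei)) {
    warning(sprintf("element '%s' not in vocabulary; mapped to Unknown", el))
    ei <- match("Unknown", config$elementVocab)
  }
  c(oneHot(ei - 1L, length(config$elementVocab)),
    oneHot(deg, config$maxDegree),
    oneHot(nh, config$maxNumH),
    oneHot(iv, config$maxImplicitValence),
    as.numeric(isTRUE(as.logical(descriptor$aromatic))))
}

# Parse SMILES through OpenBabel into per-molecule atom/bond tables.
# Returns list(ok = named list of parses, failed = character vector of ids).
# A parse is list(elements, bonds (m x 3 matrix: a1, a2, order), aromaticAtoms).
obParseSmiles <- function(smiles, ids) {
  remaining <- seq_along(smiles)
  ok <- vector("list", length(smiles))
  names(ok) <- ids
  failed <- character()
  while (length(remaining)) {
    inp <- paste0(paste(smiles[remaining], ids[remaining]), "\n", collapse = "")
    out <- suppressWarnings(
      ChemmineOB::convertFormat("SMI", "SDF", inp,
                                options = data.frame(names = "h", args = "")))
    sdfs <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(unlist(strsplit(out, "\n")))),
      error = function(e) NULL)
    got <- if (is.null(sdfs) || length(sdfs) == 0) character() else
      vapply(seq_along(sdfs), function(i) ChemmineR::sdfid(sdfs[i]), "")
    for (i in seq_along(got)) {
      j <- remaining[i]
      if (!identical(got[i], ids[j])) break
      ok[[j]] <- sdfToParse(sdfs[[i]])
    }
    nGood <- if (length(got)) {
      w <- which(got != ids[remaining][seq_along(got)])
      if (length(w)) w[1] - 1L else length(got)
    } else 0L
    if (nGood < length(remaining)) { # the molecule after the last good one failed
      bad <- remaining[nGood + 1L]
      failed <- c(failed, ids[bad])
      remaining <- remaining[-seq_len(nGood + 1L)]
    } else {
      remaining <- integer()
    }
  }
  list(ok = ok, failed = failed)
}

sdfToParse <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(numeric(0), 0, 3)
  } else {
    unname(as.matrix(bb[, 1:3, drop = FALSE]))
  }
  aromaticAtoms <- integer()
  rr <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
    error = function(e) NULL)
  if (!is.null(rr) && length(rr$RINGS)) {
    aromRings <- rr$RINGS[which(rr$AROMATIC)]
    if (length(aromRings)) {
      aromaticAtoms <- unique(as.integer(
        sub("^.*_", "", unlist(aromRings, use.names = FALSE))))
    }
  }
  list(elements = elements, bonds = bonds, aromaticAtoms = aromaticAtoms)
}

parseToGraph <- function(parse, smiles, config) {
  heavy <- which(parse$elements != "H")
  if (length(heavy) == 0L)
    stop(sprintf("SMILES '%s' yields an empty heavy-atom graph", smiles),
         call. = FALSE)
  idxMap <- match(seq_along(parse$elements), heavy) # full index -> heavy index
  n <- length(heavy)
  A <- matrix(0, n, n)
  degree <- integer(n)
  numH <- integer(n)
  b <- parse$bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      a1 <- b[r, 1]; a2 <- b[r, 2]
      h1 <- idxMap[a1]; h2 <- idxMap[a2]
      if (!is.na(h1) && !is.na(h2)) {
        A[h1, h2] <- 1; A[h2, h1] <- 1
        degree[h1] <- degree[h1] + 1L
        degree[h2] <- degree[h2] + 1L
      } else if (!is.na(h1)) {
        numH[h1] <- numH[h1] + 1L
      } else if (!is.na(h2)) {
        numH[h2] <- numH[h2] + 1L
      }
    }
  }
  aromatic <- heavy %in% parse$aromaticAtoms
  atoms <- data.frame(element = parse$elements[heavy],
                      degree = degree, numH = numH,
                      # hydrogens are implicit in the SMILES the pipeline
                      # ingests, so implicit valence equals the hydrogen count
                      implicitValence = numH,
                      aromatic = aromatic,
                      stringsAsFactors = FALSE)
  X <- t(vapply(seq_len(n), function(i) featurizeAtom(atoms[i, ], config),
                numeric(config$featureLength)))
  new("MoleculeGraph", nodeFeatures = X, adjacency = A, atoms = atoms,
      smiles = smiles)
}

#' Convert SMILES to attributed molecular graphs
#'
#' `smilesToGraph` converts one SMILES string into a [MoleculeGraph-class]:
#' one node per heavy atom (hydrogens are counted in the node features, not
#' represented as nodes), one symmetric adjacency entry pair per bond
#' regardless of bond order, and the node-feature layout of
#' [atomFeatureConfig()]. Node order follows the parser's atom order and is
#' recorded in the `atoms` slot. `parseSmilesSet` converts a whole vector in
#' one parser invocation, reporting unparsable entries instead of failing.
#'
#' @param smiles a single SMILES string (`smilesToGraph`) or a named
#'   character vector of SMILES (`parseSmilesSet`; unnamed vectors get ids
#'   m1, m2, ...).
#' @param config an [atomFeatureConfig()].
#' @return `smilesToGraph`: a [MoleculeGraph-class]. `parseSmilesSet`: a list
#'   with `graphs` (named list of MoleculeGraph) and `failed` (character ids
#'   that did not parse).
#' @examples
#' g <- smilesToGraph("CC")
#' adjacency(g)      # 2 x 2, ones off the diagonal
#' @export
smilesToGraph <- function(smiles, config = atomFeatureConfig()) {
  stopIfNot(is.character(smiles) && length(smiles) == 1L && nzchar(smiles),
            "smiles must be a single non-empty string")
  res <- obParseSmiles(smiles, "m1")
  if (length(res$failed))
    stop(sprintf("unparsable SMILES: '%s'", smiles), call. = FALSE)
  parseToGraph(res$ok[[1]], smiles, config)
}

#' @rdname smilesToGraph
#' @export
parseSmilesSet <- function(smiles, config = atomFeatureConfig()) {
  stopIfNot(length(smiles) >= 1L, "need at least one SMILES")
  ids <- names(smiles) %||% paste0("m", seq_along(smiles))
  if (is.null(names(smiles))) names(smiles) <- ids
  res <- obParseSmiles(unname(smiles), ids)
  graphs <- list()
  for (id in ids[!ids %in% res$failed]) {
    g <- tryCatch(parseToGraph(res$ok[[id]], smiles[[id]], config),
                  error = function(e) NULL)
    if (is.null(g)) res$failed <- c(res$failed, id) else graphs[[id]] <- g
  }
  if (length(res$failed))
    warning(sprintf("%d SMILES failed to parse: %s", length(res$failed),
                    paste(head(res$failed, 5L), collapse = ", ")))
  list(graphs = graphs, failed = res$failed)
}

#' Serialize a set of molecular graphs
#'
#' Graph caches are RDS files (R's portable compressed binary serialization)
#' holding the graph list and the featurizer configuration; the reader
#' refuses caches produced under a different feature layout.
#'
#' @param graphs named list of [MoleculeGraph-class] objects.
#' @param path cache file path.
#' @param config the [atomFeatureConfig()] the graphs were built with.
#' @return `writeGraphCache` returns `path` invisibly; `readGraphCache` the
#'   named graph list.
#' @export
writeGraphCache <- function(graphs, path, config = atomFeatureConfig()) {
  saveRDS(list(format = "affinitytransfer-graphcache-v1",
               fingerprint = configFingerprint(config), graphs = graphs),
          path)
  invisible(path)
}

#' @rdname writeGraphCache
#' @export
readGraphCache <- function(path, config = atomFeatureConfig()) {
  obj <- readRDS(path)
  stopIfNot(identical(obj$format, "affinitytransfer-graphcache-v1"),
            paste0("not a graph cache: ", path))
  stopIfNot(identical(obj$fingerprint, configFingerprint(config)),
            "graph cache was built under a different feature configuration")
  obj$graphs
}
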