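#' Synthetic-world configuration
#'
#' Parameters of the generative world that couples the three tasks. Chemicals
#' are built by seeded concatenation of small fragment templates into valid
#' SMILES; proteins by seeded placement of k-mer motifs into random background
#' sequence. Each entity's latent interaction vector is a deterministic
#' function of its observable structure: the normalized fragment-count
#' (motif-count) vector times a fixed loading matrix. CCI and PPI labels are
#' Bernoulli draws through a logistic link on latent inner products; DTA
#' affinities are a bilinear function of the same latents plus Gaussian
#' noise. Because one latent structure drives all three tasks, auxiliary
#' pretraining is transferable by construction.
#'
#' @param nChemicals,nProteins number of entities (defaults 300 / 200).
#' @param latentDim latent dimension m (default 8).
#' @param fragments named character vector of SMILES fragment templates; the
#'   closed default grammar (alkyl, ether, amine, carbonyl, branch, single
#'   aliphatic/aromatic rings) guarantees parser-valid concatenations, and
#'   every emitted SMILES is re-parsed as a gate regardless.
#' @param motifs character vector of protein k-mers (k = 3 by default).
#' @param beta interaction steepness of the logistic link (default 3).
#' @param bias logistic intercept. The default `NULL` calibrates it per
#'   task so that the marginal positive rate is one half: because structure
#'   counts are nonnegative, latent vectors share a mean direction and raw
#'   inner products have a positive mean; without the calibration,
#'   class-balanced sampling would fill the negative class mostly with
#'   label-flipped positives and destroy the task's separability.
#' @param labelNoise label flip probability eta in [0, 0.5) (default 0.05).
#' @param affinityNoiseSd Gaussian affinity noise sigma (default 0.3).
#' @param affinityScale,affinityIntercept affinity = scale * <u, v> +
#'   intercept + noise; defaults 1 and 6 put affinities on a pKd-like scale.
#' @param fragmentRange,motifRange integer ranges (min, max) for the number
#'   of fragments per chemical / motif placements per protein.
#' @param lengthRange protein length range.
#' @param loadingScale standard deviation of loading-matrix entries. Latents
#'   are unit-L2-normalized count vectors times the loadings, so every
#'   entity's latent norm is on the same scale and `loadingScale` sets the
#'   spread of the interaction surface.
#' @param seed integer seed; the whole world is deterministic given it.
#' @return A named list of class `SyntheticWorldConfig`.
#' @export
syntheticWorldConfig <- function(nChemicals = 300L, nProteins = 200L,
                                 latentDim = 8L,
                                 fragments = defaultFragmentSet(),
                                 motifs = defaultMotifSet(),
                                 beta = 3, bias = NULL, labelNoise = 0.05,
                                 affinityNoiseSd = 0.3, affinityScale = 1,
                                 affinityIntercept = 6,
                                 fragmentRange = c(2L, 6L),
                                 motifRange = c(4L, 12L),
                                 lengthRange = c(80L, 150L),
                                 loadingScale = 1.2, seed = 1L) {
  stopIfNot(latentDim >= 1L, "latentDim must be >= 1")
  stopIfNot(labelNoise >= 0 && labelNoise < 0.5,
            "labelNoise must lie in [0, 0.5)")
  stopIfNot(affinityNoiseSd >= 0, "affinityNoiseSd must be >= 0")
  cfg <- list(nChemicals = as.integer(nChemicals),
              nProteins = as.integer(nProteins),
              latentDim = as.integer(latentDim),
              fragments = fragments, motifs = motifs,
              beta = beta, bias = if (!is.null(bias)) as.numeric(bias),
              labelNoise = labelNoise,
              affinityNoiseSd = affinityNoiseSd,
              affinityScale = affinityScale,
              affinityIntercept = affinityIntercept,
              fragmentRange = as.integer(fragmentRange),
              motifRange = as.integer(motifRange),
              lengthRange = as.integer(lengthRange),
              loadingScale = loadingScale, seed = as.integer(seed))
  class(cfg) <- c("SyntheticWorldConfig", "list")
  cfg
}

#' Default structural templates
#'
#' `defaultFragmentSet`: eight SMILES fragments that concatenate into valid
#' molecules after a leading carbon. `defaultMotifSet`: eight amino-acid
#' 3-mers built from low-background-frequency residues with linearly
#' independent compositions, so motif content stays visible to a
#' composition-level sequence encoder.
#' @return Named character vector.
#' @export
defaultFragmentSet <- function() {
  c(methyl = "C", ethyl = "CC", ether = "OC", amine = "NC",
    carbonyl = "C(=O)C", branch = "C(C)C", cyclopentyl = "C1CCCC1",
    phenyl = "c1ccccc1")
}

#' @rdname defaultFragmentSet
#' @export
defaultMotifSet <- function() {
  c("WWC", "HHM", "YYF", "PPQ", "WHY", "CMF", "WPQ", "HFQ")
}

l2NormalizeRows <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)

rdirichletCounts <- function(nTypes, total, alpha = 0.5) {
  w <- rgamma(nTypes, alpha)
  if (sum(w) == 0) w <- rep(1, nTypes)
  drop(stats::rmultinom(1, total, w / sum(w)))
}

#' Generate a synthetic world
#'
#' Builds all chemicals, proteins, their latent vectors and structure-count
#' matrices from the configuration seed. Every emitted SMILES is re-parsed
#' through [parseSmilesSet()] as a generation-time assertion; an invalid
#' fragment grammar therefore fails loudly here rather than downstream.
#'
#' @param config a [syntheticWorldConfig()].
#' @return A [SyntheticWorld-class].
#' @examples
#' w <- generateWorld(syntheticWorldConfig(nChemicals = 10, nProteins = 6,
#'                                         seed = 7))
#' nrow(worldChemicals(w)) # 10
#' @export
generateWorld <- function(config) {
  stopIfNot(inherits(config, "SyntheticWorldConfig"),
            "config must come from syntheticWorldConfig()")
  set.seed(deriveSeed(config$seed, 21L))
  m <- config$latentDim
  nF <- length(config$fragments)
  nM <- length(config$motifs)
  Lc <- matrix(rnorm(nF * m, sd = config$loadingScale), nF, m)
  Lp <- matrix(rnorm(nM * m, sd = config$loadingScale), nM, m)

  chemIds <- sprintf("CHEM%04d", seq_len(config$nChemicals))
  fragCounts <- matrix(0L, config$nChemicals, nF,
                       dimnames = list(chemIds, names(config$fragments)))
  smiles <- character(config$nChemicals)
  for (i in seq_len(config$nChemicals)) {
    nf <- sample(config$fragmentRange[1]:config$fragmentRange[2], 1L)
    counts <- rdirichletCounts(nF, nf)
    inst <- sample(rep.int(seq_len(nF), counts))
    smiles[i] <- paste0("C", paste(config$fragments[inst], collapse = ""))
    fragCounts[i, ] <- counts
  }
  parsed <- suppressWarnings(parseSmilesSet(setNames(smiles, chemIds)))
  if (length(parsed$failed))
    stop("fragment grammar emitted invalid SMILES: ",
         paste(head(parsed$failed, 5L), collapse = ", "), call. = FALSE)
  chemLatents <- l2NormalizeRows(fragCounts) %*% Lc

  protIds <- sprintf("PROT%04d", seq_len(config$nProteins))
  aa <- aminoAcidVocab()[1:20]
  motifCounts <- matrix(0L, config$nProteins, nM,
                        dimnames = list(protIds, config$motifs))
  seqs <- character(config$nProteins)
  k <- nchar(config$motifs[1])
  for (j in seq_len(config$nProteins)) {
    len <- sample(config$lengthRange[1]:config$lengthRange[2], 1L)
    chars <- sample(aa, len, replace = TRUE)
    nm <- sample(config$motifRange[1]:config$motifRange[2], 1L)
    counts <- rdirichletCounts(nM, nm)
    inst <- sample(rep.int(seq_len(nM), counts))
    taken <- logical(len)
    placed <- integer(nM)
    for (mi in inst) {
      free <- which(!taken[seq_len(len - k + 1L)])
      free <- free[vapply(free, function(s) !any(taken[s:(s + k - 1L)]), TRUE)]
      if (!length(free)) break
      s <- free[sample.int(length(free), 1L)]
      chars[s:(s + k - 1L)] <- strsplit(config$motifs[mi], "")[[1]]
      taken[s:(s + k - 1L)] <- TRUE
      placed[mi] <- placed[mi] + 1L
    }
    motifCounts[j, ] <- placed
    seqs[j] <- paste(chars, collapse = "")
  }
  protLatents <- l2NormalizeRows(motifCounts) %*% Lp

  new("SyntheticWorld",
      chemicals = data.frame(id = chemIds, smiles = smiles,
                             stringsAsFactors = FALSE),
      proteins = data.frame(id = protIds, sequence = seqs,
                            stringsAsFactors = FALSE),
      chemLatents = chemLatents, protLatents = protLatents,
      fragCounts = fragCounts, motifCounts = motifCounts,
      loadings = list(fragment = Lc, motif = Lp),
      config = unclass(config))
}

#' Sample interaction pairs (CCI or PPI) from a world
#'
#' Pairs of distinct entities are drawn uniformly; each pair interacts with
#' probability `plogis(beta * <latent_i, latent_j> + bias)`; drawn labels are
#' then flipped with probability `labelNoise`. Classes are balanced 1:1 by
#' rejection sampling (configurable via `positiveFraction`). CCI records
#' carry an evidence-channel tag (experimental / similarity / text / other)
#' sampled independently of the label, supporting channel-restricted
#' pretraining.
#'
#' @param world a [SyntheticWorld-class].
#' @param task "cci" or "ppi".
#' @param nPairs number of labeled pairs to emit.
#' @param seed integer seed.
#' @param positiveFraction target fraction of positive labels (default 0.5).
#' @param channelProbs named numeric probabilities for CCI evidence channels.
#' @return A [PairDataset-class].
#' @export
sampleInteractionPairs <- function(world, task = c("cci", "ppi"), nPairs,
                                   seed = 1L, positiveFraction = 0.5,
                                   channelProbs = c(experimental = 0.4,
                                                    similarity = 0.3,
                                                    text = 0.2, other = 0.1)) {
  task <- match.arg(task)
  cfg <- world@config
  L <- if (task == "cci") world@chemLatents else world@protLatents
  ids <- if (task == "cci") world@chemicals$id else world@proteins$id
  n <- nrow(L)
  stopIfNot(n >= 2L, "need at least two entities")
  set.seed(deriveSeed(seed, if (task == "cci") 22L else 23L))
  bias <- cfg$bias
  if (is.null(bias)) {
    # calibrate the intercept to a balanced marginal positive rate
    ci <- sample.int(n, 4000L, replace = TRUE)
    cj <- sample.int(n, 4000L, replace = TRUE)
    keep <- ci != cj
    bias <- -cfg$beta * mean(rowSums(L[ci[keep], , drop = FALSE] *
                                       L[cj[keep], , drop = FALSE]))
  }
  nPos <- round(nPairs * positiveFraction)
  nNeg <- nPairs - nPos
  pos <- list(); neg <- list()
  gotPos <- 0L; gotNeg <- 0L
  tries <- 0L
  maxTries <- 400L * nPairs
  while ((gotPos < nPos || gotNeg < nNeg) && tries < maxTries) {
    chunk <- min(4L * nPairs, maxTries - tries)
    i <- sample.int(n, chunk, replace = TRUE)
    j <- sample.int(n, chunk, replace = TRUE)
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    tries <- tries + chunk
    p <- plogis(cfg$beta * rowSums(L[i, , drop = FALSE] * L[j, , drop = FALSE]) +
                  bias)
    y <- stats::rbinom(length(p), 1L, p)
    flip <- stats::rbinom(length(p), 1L, cfg$labelNoise) == 1L
    y[flip] <- 1L - y[flip]
    wPos <- which(y == 1L)[seq_len(min(sum(y == 1L), nPos - gotPos))]
    wNeg <- which(y == 0L)[seq_len(min(sum(y == 0L), nNeg - gotNeg))]
    if (length(wPos)) { pos[[length(pos) + 1L]] <- cbind(i[wPos], j[wPos]); gotPos <- gotPos + length(wPos) }
    if (length(wNeg)) { neg[[length(neg) + 1L]] <- cbind(i[wNeg], j[wNeg]); gotNeg <- gotNeg + length(wNeg) }
  }
  if (gotPos < nPos || gotNeg < nNeg)
    stop(sprintf("could not balance classes: achieved %d positive / %d negative of %d requested",
                 gotPos, gotNeg, nPairs), call. = FALSE)
  mat <- rbind(do.call(rbind, pos), do.call(rbind, neg))
  lab <- c(rep(1L, nPos), rep(0L, nNeg))
  ord <- sample.int(nrow(mat)) # interleave classes
  pairs <- data.frame(left = ids[mat[ord, 1]], right = ids[mat[ord, 2]],
                      label = lab[ord], stringsAsFactors = FALSE)
  if (task == "cci")
    pairs$channel <- sample(names(channelProbs), nrow(pairs), replace = TRUE,
                            prob = channelProbs)
  new("PairDataset", task = task, pairs = pairs,
      chemicals = if (task == "cci")
        setNames(world@chemicals$smiles, world@chemicals$id) else character(),
      proteins = if (task == "ppi")
        setNames(world@proteins$sequence, world@proteins$id) else character())
}

#' Sample drug-target affinity pairs from a world
#'
#' Draws distinct (chemical, protein) combinations uniformly and assigns
#' `affinity = affinityScale * <u_i, v_j> + affinityIntercept +
#' Normal(0, affinityNoiseSd)`. The same latents drive the CCI and PPI
#' labels, which is the mechanism that makes auxiliary pretraining
#' transferable.
#'
#' @param world a [SyntheticWorld-class].
#' @param nPairs number of affinity records.
#' @param seed integer seed.
#' @return A [PairDataset-class] with task "dta" (left = chemical id,
#'   right = protein id).
#' @export
sampleDtaPairs <- function(world, nPairs, seed = 1L) {
  cfg <- world@config
  nC <- nrow(world@chemLatents)
  nP <- nrow(world@protLatents)
  stopIfNot(nPairs <= nC * nP, "more pairs requested than distinct combinations")
  set.seed(deriveSeed(seed, 24L))
  cell <- sample.int(nC * nP, nPairs)
  i <- ((cell - 1L) %% nC) + 1L
  j <- ((cell - 1L) %/% nC) + 1L
  dot <- rowSums(world@chemLatents[i, , drop = FALSE] *
                   world@protLatents[j, , drop = FALSE])
  y <- cfg$affinityScale * dot + cfg$affinityIntercept +
    rnorm(nPairs, sd = cfg$affinityNoiseSd)
  pairs <- data.frame(left = world@chemicals$id[i],
                      right = world@proteins$id[j],
                      label = y, stringsAsFactors = FALSE)
  new("PairDataset", task = "dta", pairs = pairs,
      chemicals = setNames(world@chemicals$smiles, world@chemicals$id),
      proteins = setNames(world@proteins$sequence, world@proteins$id))
}

#' Restrict a CCI dataset to given evidence channels
#'
#' Keeps only records whose channel tag is in `channels`; everything else
#' about the dataset is unchanged. This is the switch behind the
#' full-corpus-vs-experimental-only pretraining comparison.
#'
#' @param dataset a CCI [PairDataset-class].
#' @param channels character vector of channel tags to keep.
#' @return A [PairDataset-class].
#' @export
filterEvidence <- function(dataset, channels = "experimental") {
  stopIfNot(dataset@task == "cci", "evidence channels only exist for CCI data")
  stopIfNot(!is.null(dataset@pairs$channel), "dataset has no channel column")
  keep <- dataset@pairs$channel %in% channels
  stopIfNot(any(keep), "no records left after channel filtering")
  new("PairDataset", task = "cci",
      pairs = dataset@pairs[keep, , drop = FALSE],
      chemicals = dataset@chemicals, proteins = dataset@proteins)
}
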