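#' Entity-disjoint cold-start and warm splitting
#'
#' Assigns every record of a DTA dataset to train/valid/test. In the
#' `cold_drug` (resp. `cold_target`) regime the distinct drugs (proteins) are
#' shuffled under the seed and partitioned by the given fractions, and each
#' record follows its entity; every drug (protein) seen at validation or test
#' time is therefore absent from training. The three entity sets are mutually
#' disjoint (a three-way entity partition, not only valid/test vs train). In
#' the `warm` regime records are split at pair level, so with a dense enough
#' interaction matrix test entities also occur in training.
#'
#' @param dataset a [PairDataset-class] with task "dta".
#' @param regime "cold_drug", "cold_target" or "warm".
#' @param fractions numeric length-3 (train, valid, test), positive, summing
#'   to 1. Default `c(0.6, 0.2, 0.2)`.
#' @param seed integer seed; identical seed gives an identical manifest.
#' @return A [SplitManifest-class].
#' @examples
#' w <- generateWorld(syntheticWorldConfig(nChemicals = 12, nProteins = 8,
#'                                         seed = 1))
#' d <- sampleDtaPairs(w, 60, seed = 2)
#' m <- coldSplit(d, "cold_drug", seed = 3)
#' auditSplit(m, d)
#' @export
coldSplit <- function(dataset, regime = c("cold_drug", "cold_target", "warm"),
                      fractions = c(train = 0.6, valid = 0.2, test = 0.2),
                      seed = 1L) {
  regime <- match.arg(regime)
  stopIfNot(is(dataset, "PairDataset") && dataset@task == "dta",
            "coldSplit expects a DTA PairDataset")
  fractions <- as.numeric(fractions)
  stopIfNot(length(fractions) == 3L && all(fractions > 0) &&
              abs(sum(fractions) - 1) < 1e-8,
            "fractions must be 3 positive numbers summing to 1")
  names(fractions) <- c("train", "valid", "test")
  pairs <- dataset@pairs
  n <- nrow(pairs)

  seed <- as.integer(seed)
  rng <- deriveSeed(seed, 101L)

  if (regime == "warm") {
    set.seed(rng)
    ord <- sample.int(n)
    cut1 <- floor(fractions[1] * n)
    cut2 <- floor((fractions[1] + fractions[2]) * n)
    stopIfNot(cut1 >= 1 && cut2 > cut1 && cut2 < n,
              sprintf("dataset too small to fill all partitions (%d records)", n))
    parts <- list(train = sort(ord[seq_len(cut1)]),
                  valid = sort(ord[(cut1 + 1):cut2]),
                  test  = sort(ord[(cut2 + 1):n]))
    entities <- list()
  } else {
    axis <- if (regime == "cold_drug") pairs$left else pairs$right
    ents <- unique(axis)
    k <- length(ents)
    if (k < 3L)
      stop(sprintf("regime %s needs >= 3 distinct entities on the cold axis, got %d",
                   regime, k), call. = FALSE)
    set.seed(rng)
    ents <- ents[sample.int(k)]
    nTrain <- max(1L, floor(fractions[1] * k))
    nValid <- max(1L, floor(fractions[2] * k))
    if (nTrain + nValid >= k) { # guarantee a non-empty test partition
      nValid <- max(1L, k - nTrain - 1L)
      nTrain <- k - nValid - 1L
    }
    entities <- list(train = ents[seq_len(nTrain)],
                     valid = ents[nTrain + seq_len(nValid)],
                     test  = ents[(nTrain + nValid + 1L):k])
    whichPart <- function(ids) which(axis %in% ids)
    parts <- lapply(entities, whichPart)
  }

  new("SplitManifest", regime = regime, fractions = fractions, seed = seed,
      train = as.integer(parts$train), valid = as.integer(parts$valid),
      test = as.integer(parts$test), entities = entities)
}

#' Audit a split manifest for entity leakage
#'
#' Recomputes the disjointness predicates of a manifest's regime directly
#' from the dataset, independently of how the manifest was produced: coverage
#' and non-overlap of the three partitions always; entity disjointness on the
#' cold axis for the cold regimes; train coverage of test entities for warm
#' (reported, not enforced, since sparse data may not permit it).
#'
#' @param manifest a [SplitManifest-class].
#' @param dataset the [PairDataset-class] it indexes.
#' @return A list with logical fields `covers`, `disjointRecords`,
#'   `coldDisjoint` (NA for warm), `warmCovered` (NA for cold) and `ok`, the
#'   conjunction of the applicable predicates.
#' @export
auditSplit <- function(manifest, dataset) {
  pairs <- dataset@pairs
  n <- nrow(pairs)
  idx <- c(manifest@train, manifest@valid, manifest@test)
  covers <- setequal(idx, seq_len(n))
  disjointRecords <- !anyDuplicated(idx)
  coldDisjoint <- NA
  warmCovered <- NA
  if (manifest@regime %in% c("cold_drug", "cold_target")) {
    axis <- if (manifest@regime == "cold_drug") pairs$left else pairs$right
    trainEnt <- unique(axis[manifest@train])
    validEnt <- unique(axis[manifest@valid])
    testEnt  <- unique(axis[manifest@test])
    coldDisjoint <- length(intersect(trainEnt, union(validEnt, testEnt))) == 0L &&
      length(intersect(validEnt, testEnt)) == 0L
  } else {
    trainDrugs <- unique(pairs$left[manifest@train])
    trainProts <- unique(pairs$right[manifest@train])
    warmCovered <- all(pairs$left[manifest@test] %in% trainDrugs) &&
      all(pairs$right[manifest@test] %in% trainProts)
  }
  ok <- covers && disjointRecords && (is.na(coldDisjoint) || coldDisjoint)
  list(covers = covers, disjointRecords = disjointRecords,
       coldDisjoint = coldDisjoint, warmCovered = warmCovered, ok = ok)
}

#' Write / read a split manifest
#'
#' Manifests serialize to JSON with regime, fractions, seed, the explicit
#' record-index lists and the cold-axis entity lists — sufficient to
#' reproduce the split without re-running the splitter.
#'
#' @param manifest a [SplitManifest-class].
#' @param path file path.
#' @return `writeSplitManifest` returns `path` invisibly;
#'   `readSplitManifest` returns the manifest.
#' @export
writeSplitManifest <- function(manifest, path) {
  obj <- list(format = "affinitytransfer-split-v1",
              regime = manifest@regime,
              fractions = as.list(manifest@fractions),
              seed = manifest@seed,
              train = manifest@train, valid = manifest@valid,
              test = manifest@test,
              entities = manifest@entities)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplitManifest
#' @export
readSplitManifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopIfNot(identical(obj$format, "affinitytransfer-split-v1"),
            paste0("not a split manifest file: ", path))
  ent <- obj$entities
  if (length(ent) == 0) ent <- list() else ent <- lapply(ent, as.character)
  new("SplitManifest", regime = obj$regime,
      fractions = unlist(obj$fractions), seed = as.integer(obj$seed),
      train = as.integer(obj$train), valid = as.integer(obj$valid),
      test = as.integer(obj$test), entities = ent)
}
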