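## Intervention-triplet datasets: container, SCM-based generators, latent
## confounder corruption, and TSV round-trip I/O.

#' Construct a PerturbationDataset
#'
#' @param initial,outcome genes x samples matrices in `[0, 1]` (initial =
#'   pre-intervention state, outcome = post-intervention state).
#' @param targets list of character vectors: the perturbed gene set per
#'   sample; or a single vector recycled to all samples.
#' @param kind `"disease"` or `"perturbagen"`, per sample or scalar.
#' @param context cell-line-like label, per sample or scalar.
#' @param perturbagenId optional per-sample label identifying which library
#'   perturbagen generated the sample (defaults to the joined target set).
#' @return a [PerturbationDataset-class].
#' @export
PerturbationDataset <- function(initial, outcome, targets, kind = "perturbagen",
                                context = "ctx1", perturbagenId = NULL) {
  stopifnot(all(dim(initial) == dim(outcome)))
  S <- ncol(initial)
  if (!is.list(targets)) targets <- rep(list(as.character(targets)), S)
  joined <- vapply(targets, paste, "", collapse = ",")
  if (is.null(perturbagenId)) perturbagenId <- joined
  if (is.null(colnames(initial)))
    colnames(initial) <- colnames(outcome) <- sprintf("s%d", seq_len(S))
  cd <- S4Vectors::DataFrame(
    kind = rep(kind, length.out = S),
    context = rep(context, length.out = S),
    targets = joined,
    perturbagenId = rep(perturbagenId, length.out = S),
    row.names = colnames(initial))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(initial = initial, outcome = outcome), colData = cd)
  new("PerturbationDataset", se)
}

#' Accessors for PerturbationDataset
#'
#' `initialState`/`outcomeState` return the genes x samples expression
#' matrices; `interventionSets` the per-sample perturbed gene sets (list of
#' character vectors); `sampleKind` and `sampleContext` the per-sample labels.
#'
#' @param x a [PerturbationDataset-class].
#' @name PerturbationDataset-accessors
#' @aliases initialState outcomeState interventionSets sampleKind sampleContext
NULL

#' @rdname PerturbationDataset-accessors
#' @export
setMethod("initialState", "PerturbationDataset",
          function(x) SummarizedExperiment::assay(x, "initial"))
#' @rdname PerturbationDataset-accessors
#' @export
setMethod("outcomeState", "PerturbationDataset",
          function(x) SummarizedExperiment::assay(x, "outcome"))
#' @rdname PerturbationDataset-accessors
#' @export
setMethod("interventionSets", "PerturbationDataset",
          function(x) strsplit(SummarizedExperiment::colData(x)$targets, ","))
#' @rdname PerturbationDataset-accessors
#' @export
setMethod("sampleKind", "PerturbationDataset",
          function(x) SummarizedExperiment::colData(x)$kind)
#' @rdname PerturbationDataset-accessors
#' @export
setMethod("sampleContext", "PerturbationDataset",
          function(x) SummarizedExperiment::colData(x)$context)

## Per-sample clamp values for an intervention: a fixed per-gene direction
## (strong up- or down-shift) with per-sample magnitudes from Beta(5, 0.5)
## (up) or Beta(0.5, 5) (down), emulating activation/knockout without hard
## 0/1-only states. Explicit clampValues (named vector) override the draws.
drawClamps <- function(genes, S, seed, clampValues = NULL) {
  k <- length(genes)
  if (!is.null(clampValues)) {
    if (!all(genes %in% names(clampValues)))
      stopf("clampValues must cover every intervened gene")
    return(matrix(rep(as.numeric(clampValues[genes]), S), k, S))
  }
  withSeed(seed, {
    up <- sample(c(TRUE, FALSE), k, replace = TRUE)
    v <- matrix(0, k, S)
    for (j in seq_len(k))
      v[j, ] <- if (up[j]) stats::rbeta(S, 5, 0.5) else stats::rbeta(S, 0.5, 5)
    v
  })
}

#' Generate disease intervention triplets from an SCM
#'
#' Simulates `m` paired healthy/diseased samples: the healthy state is the
#' unperturbed system with a fresh exogenous draw per sample; the diseased
#' state applies the disease-gene intervention with strong per-gene up/down
#' clamps. With `sharedNoise = TRUE` (default) each pair shares its exogenous
#' draw, so healthy and diseased states differ only through the intervention.
#'
#' @param scm an [SCMParams-class].
#' @param diseaseGenes an [InterventionSet-class] (kind `"disease"`) or
#'   character vector.
#' @param m number of samples (>= 1).
#' @param seed integer seed.
#' @param context sample context label.
#' @param sharedNoise share exogenous draws between the pair's two states.
#' @param clampValues optional named vector of fixed clamp values in `[0, 1]`.
#' @return a [PerturbationDataset-class] with `kind == "disease"`.
#' @export
generateDiseaseDataset <- function(scm, diseaseGenes, m, seed,
                                   context = "ctx1", sharedNoise = TRUE,
                                   clampValues = NULL) {
  stopifnot(m >= 1)
  nodes <- nodeIds(scm@graph)
  genes <- if (is(diseaseGenes, "InterventionSet")) members(diseaseGenes)
           else as.character(diseaseGenes)
  uIdx <- match(genes, nodes)
  if (anyNA(uIdx)) stopf("disease gene(s) not in graph")
  epsH <- drawNoise(scm, m, childSeed(seed, "noise-h"))
  epsD <- if (sharedNoise) epsH else drawNoise(scm, m, childSeed(seed, "noise-d"))
  xh <- simulateMatrix(scm, integer(0), matrix(0, 0, m), epsH)
  clampMat <- drawClamps(genes, m, childSeed(seed, "clamp"), clampValues)
  xd <- simulateMatrix(scm, uIdx, clampMat, epsD)
  PerturbationDataset(xh, xd, targets = list(genes)[rep(1L, m)],
                      kind = "disease", context = context,
                      perturbagenId = "disease")
}

#' Generate treatment intervention triplets from an SCM
#'
#' For each perturbagen in the library, simulates `mPerPerturbagen` paired
#' diseased/treated samples: the diseased state applies the disease-gene
#' intervention; the treated state re-simulates the same exogenous draw under
#' the perturbagen intervention alone (do-operator on the perturbagen's
#' genes). Each sample is tagged with its perturbagen so that held-out
#' perturbagen splits can be built.
#'
#' @param scm an [SCMParams-class].
#' @param library non-empty named list of [InterventionSet-class] objects (or
#'   character vectors) -- the perturbagen library.
#' @param mPerPerturbagen samples per perturbagen (>= 1).
#' @param seed integer seed.
#' @param diseaseGenes the disease intervention applied to diseased states.
#' @param context sample context label.
#' @param clampValues optional list, named by perturbagen, of named clamp
#'   vectors (fixed clamp values for that perturbagen's genes).
#' @return a [PerturbationDataset-class] with `kind == "perturbagen"`.
#' @export
generateTreatmentDataset <- function(scm, library, mPerPerturbagen, seed,
                                     diseaseGenes, context = "ctx1",
                                     clampValues = NULL) {
  if (length(library) == 0L) stopf("perturbagen library must be non-empty")
  stopifnot(mPerPerturbagen >= 1)
  nodes <- nodeIds(scm@graph)
  dGenes <- if (is(diseaseGenes, "InterventionSet")) members(diseaseGenes)
            else as.character(diseaseGenes)
  dIdx <- match(dGenes, nodes)
  if (anyNA(dIdx)) stopf("disease gene(s) not in graph")
  if (is.null(names(library)))
    names(library) <- sprintf("P%d", seq_along(library))
  m <- mPerPerturbagen
  xdAll <- xtAll <- NULL; targets <- list(); pid <- character(0)
  for (p in names(library)) {
    genes <- if (is(library[[p]], "InterventionSet")) members(library[[p]])
             else as.character(library[[p]])
    if (length(genes) == 0L) stopf("perturbagen '%s' is empty", p)
    uIdx <- match(genes, nodes)
    if (anyNA(uIdx)) stopf("perturbagen gene(s) not in graph: %s",
                           paste(genes[is.na(uIdx)], collapse = ", "))
    eps <- drawNoise(scm, m, childSeed(seed, paste0("noise-", p)))
    dClamp <- drawClamps(dGenes, m, childSeed(seed, "clamp-disease"))
    xd <- simulateMatrix(scm, dIdx, dClamp, eps)
    tClamp <- drawClamps(genes, m, childSeed(seed, paste0("clamp-", p)),
                         clampValues[[p]])
    xt <- simulateMatrix(scm, uIdx, tClamp, eps)
    xdAll <- cbind(xdAll, xd); xtAll <- cbind(xtAll, xt)
    targets <- c(targets, rep(list(genes), m))
    pid <- c(pid, rep(p, m))
  }
  colnames(xdAll) <- colnames(xtAll) <- sprintf("s%d", seq_len(ncol(xdAll)))
  PerturbationDataset(xdAll, xtAll, targets = targets, kind = "perturbagen",
                      context = context, perturbagenId = pid)
}

#' Specify latent-confounder corruption
#'
#' Genes are partitioned into `nGroups` contiguous near-equal index blocks,
#' each representing a latent confounder group with its own Gaussian
#' `(mu_g, sd_g)` drawn from `meanRange`/`sdRange`. A seeded random fraction
#' of groups is selected and every expression value of their genes is
#' incremented by a fresh draw from the group's Gaussian, then clamped to
#' `[0, 1]`.
#'
#' @param nGroups number of confounder groups (default 50).
#' @param meanRange interval for group means (default `c(-0.5, 0.5)`).
#' @param sdRange interval for group standard deviations (default
#'   `c(0.1, 0.5)`).
#' @param fractionPerturbed fraction of groups to corrupt, in `(0, 1]`.
#' @param seed integer seed.
#' @return a `ConfounderSpec` list.
#' @export
confounderSpec <- function(nGroups = 50L, meanRange = c(-0.5, 0.5),
                           sdRange = c(0.1, 0.5), fractionPerturbed = 1,
                           seed = 1L) {
  stopifnot(nGroups >= 1, fractionPerturbed > 0, fractionPerturbed <= 1,
            length(meanRange) == 2L, length(sdRange) == 2L,
            all(sdRange >= 0))
  structure(list(nGroups = as.integer(nGroups), meanRange = meanRange,
                 sdRange = sdRange, fractionPerturbed = fractionPerturbed,
                 seed = as.integer(seed)),
            class = "ConfounderSpec")
}

#' Inject latent-confounder noise into a dataset
#'
#' @param dataset a [PerturbationDataset-class].
#' @param spec a [confounderSpec()].
#' @return the corrupted [PerturbationDataset-class]; intervention sets and
#'   labels are untouched and all values stay in `[0, 1]`.
#' @export
injectConfounders <- function(dataset, spec) {
  stopifnot(inherits(spec, "ConfounderSpec"))
  n <- nrow(dataset); S <- ncol(dataset)
  groups <- sort(rep_len(seq_len(spec$nGroups), n))  # contiguous blocks
  res <- withSeed(spec$seed, {
    mu <- stats::runif(spec$nGroups, spec$meanRange[1], spec$meanRange[2])
    sdv <- stats::runif(spec$nGroups, spec$sdRange[1], spec$sdRange[2])
    sel <- sample.int(spec$nGroups, round(spec$fractionPerturbed * spec$nGroups))
    hit <- groups %in% sel
    noise <- function() {
      e <- matrix(0, n, S)
      e[hit, ] <- stats::rnorm(sum(hit) * S, mu[groups[hit]], sdv[groups[hit]])
      e
    }
    list(eInit = noise(), eOut = noise())
  })
  a <- SummarizedExperiment::assays(dataset)
  dn <- dimnames(a$initial)
  a$initial <- structure(clamp01(a$initial + res$eInit), dimnames = dn)
  a$outcome <- structure(clamp01(a$outcome + res$eOut), dimnames = dn)
  SummarizedExperiment::assays(dataset, withDimnames = FALSE) <- a
  validObject(dataset)
  dataset
}

fmtNum <- function(m) {
  out <- sprintf("%.17g", m)
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Write / read a PerturbationDataset directory
#'
#' The on-disk layout is plain text: `expression_initial.tsv` and
#' `expression_outcome.tsv` (genes x samples, 17-significant-digit values so
#' the round trip is exact), `interventions.tsv` (sample_id, kind, context,
#' targets as a comma-joined gene list, perturbagen id) and `manifest.yaml`
#' (dimensions and provenance). `readDataset(writeDataset(x)) == x`.
#'
#' @param dataset a [PerturbationDataset-class].
#' @param dir dataset directory (created if needed).
#' @param extra optional named list merged into the manifest (e.g. seeds).
#' @return `dir` (write) / the [PerturbationDataset-class] (read).
#' @export
writeDataset <- function(dataset, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f) {
    df <- data.frame(gene = rownames(m), fmtNum(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(initialState(dataset), "expression_initial.tsv")
  wr(outcomeState(dataset), "expression_outcome.tsv")
  cd <- SummarizedExperiment::colData(dataset)
  utils::write.table(
    data.frame(sample_id = rownames(cd), kind = cd$kind, context = cd$context,
               targets = cd$targets, perturbagen_id = cd$perturbagenId,
               stringsAsFactors = FALSE),
    file.path(dir, "interventions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  manifest <- c(list(format = "perturbDiscover-dataset-v1",
                     n_genes = nrow(dataset), n_samples = ncol(dataset)),
                extra)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stopf("missing manifest.yaml in %s", dir)
  manifest <- yaml::read_yaml(mf)
  rd <- function(f) {
    df <- utils::read.table(file.path(dir, f), header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stopf("non-numeric expression values in %s", f)
    if (length(m) && (min(m) < 0 || max(m) > 1))
      stopf("expression values outside [0, 1] in %s", f)
    rownames(m) <- df[[1L]]
    m
  }
  init <- rd("expression_initial.tsv")
  out <- rd("expression_outcome.tsv")
  iv <- utils::read.table(file.path(dir, "interventions.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "kind", "context", "targets", "perturbagen_id")
  if (!all(need %in% colnames(iv))) stopf("interventions.tsv schema mismatch")
  if (nrow(iv) != ncol(init) ||
      manifest$n_genes != nrow(init) || manifest$n_samples != ncol(init))
    stopf("manifest/matrix dimensions disagree")
  PerturbationDataset(init, out, targets = strsplit(iv$targets, ","),
                      kind = iv$kind, context = iv$context,
                      perturbagenId = iv$perturbagen_id)
}
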