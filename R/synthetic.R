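#' Specification of a planted-cluster benchmark
#'
#' Describes a synthetic lncRNA-disease world in which diseases and lncRNAs
#' fall into clusters: same-cluster (disease, lncRNA) pairs are associated
#' with probability \code{pIn}, all other pairs with \code{pOut}, and
#' same-cluster diseases sit under a common subtree of a generated
#' hierarchy, so the semantic similarity genuinely carries the planted
#' signal. Defaults give a benchmark recoverable by the full pipeline in
#' minutes on one core.
#'
#' @param nDiseases,nLncrnas entity counts.
#' @param nClusters number of planted clusters (entities are assigned
#'   round-robin).
#' @param pIn,pOut within- and between-cluster association probabilities
#'   (\code{0 <= pOut < pIn <= 1}).
#' @param branching,depth shape of the per-cluster subtree: each cluster
#'   root carries a complete \code{branching}-ary tree of the given depth
#'   whose leaves host the cluster's diseases.
#' @param noiseRate probability of flipping each association cell after
#'   planting (label noise), default 0.
#' @param seed generator seed.
#' @return list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(nDiseases = 60L, nLncrnas = 120L, nClusters = 10L,
                          pIn = 0.5, pOut = 0.01, branching = 3L, depth = 3L,
                          noiseRate = 0, seed = 7L) {
  stopifnot2(pOut >= 0 && pOut < pIn && pIn <= 1, "need 0 <= pOut < pIn <= 1")
  stopifnot2(nClusters <= min(nDiseases, nLncrnas),
             "more clusters than diseases or lncRNAs")
  stopifnot2(nDiseases >= 1 && nLncrnas >= 1 && nClusters >= 1 &&
               branching >= 1 && depth >= 1, "all counts must be positive")
  spec <- list(nDiseases = as.integer(nDiseases), nLncrnas = as.integer(nLncrnas),
               nClusters = as.integer(nClusters), pIn = pIn, pOut = pOut,
               branching = as.integer(branching), depth = as.integer(depth),
               noiseRate = noiseRate, seed = as.integer(seed))
  class(spec) <- "syntheticSpec"
  spec
}

# deterministic names
.diseaseName <- function(i) sprintf("disease%03d", i)
.lncName <- function(j) sprintf("lnc%03d", j)

#' Generate a clustered disease hierarchy
#'
#' Builds a single rooted tree, mirroring one MeSH category: all codes share
#' the root segment \code{C}, each cluster owns a depth-1 subtree
#' \code{C.<cluster>}, and below it a complete \code{branching}-ary tree of
#' the requested depth whose leaves host the cluster's diseases
#' (deterministic given the spec). Same-cluster diseases therefore share
#' their depth-1 ancestor, while any two diseases still share the root, as
#' same-category diseases do in a real hierarchy.
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{hierarchy} (a \linkS4class{DiseaseHierarchy}) and
#'   \code{diseaseCluster} (named integer assignment).
#' @export
generateHierarchy <- function(spec) {
  leavesPerCluster <- spec$branching^spec$depth
  cluster <- ((seq_len(spec$nDiseases) - 1L) %% spec$nClusters) + 1L
  maxPerCluster <- max(tabulate(cluster, spec$nClusters))
  stopifnot2(maxPerCluster <= leavesPerCluster,
             sprintf("cluster subtrees have %d leaves but must host %d diseases: increase branching or depth",
                     leavesPerCluster, maxPerCluster))
  # leaf index -> dot path through the b-ary tree
  leafPath <- function(leaf) {
    digits <- integer(spec$depth)
    x <- leaf - 1L
    for (k in spec$depth:1) { digits[k] <- x %% spec$branching; x <- x %/% spec$branching }
    paste(sprintf("%02d", digits + 1L), collapse = ".")
  }
  records <- list()
  slot <- integer(spec$nClusters) # next free leaf per cluster
  for (i in seq_len(spec$nDiseases)) {
    cl <- cluster[i]
    slot[cl] <- slot[cl] + 1L
    code <- sprintf("C.%02d.%s", cl, leafPath(slot[cl]))
    records[[normalizeDiseaseKey(.diseaseName(i))]] <- code
  }
  names(cluster) <- vapply(seq_len(spec$nDiseases), .diseaseName, character(1))
  list(hierarchy = new("DiseaseHierarchy", records = records),
       diseaseCluster = cluster)
}

#' Plant clustered associations
#'
#' Each (disease, lncRNA) cell is associated with probability \code{pIn}
#' when both belong to the same cluster and \code{pOut} otherwise; label
#' noise (if any) flips cells afterwards.
#'
#' @param spec a [syntheticSpec()].
#' @param diseaseCluster named integer cluster assignment of the diseases
#'   (from [generateHierarchy()]).
#' @return list with the \linkS4class{InteractionMatrix} and the lncRNA
#'   cluster assignment.
#' @export
generatePlantedAssociations <- function(spec, diseaseCluster) {
  lncCluster <- ((seq_len(spec$nLncrnas) - 1L) %% spec$nClusters) + 1L
  names(lncCluster) <- vapply(seq_len(spec$nLncrnas), .lncName, character(1))
  same <- outer(diseaseCluster, lncCluster, "==")
  pm <- ifelse(same, spec$pIn, spec$pOut)
  stopifnot2(sum(pm) > 0, "spec yields zero expected positives")
  m <- withSeed(spec$seed, {
    m <- matrix(as.numeric(stats::runif(length(pm)) < pm), nrow(pm), ncol(pm))
    if (spec$noiseRate > 0) {
      flip <- stats::runif(length(pm)) < spec$noiseRate
      m[flip] <- 1 - m[flip]
    }
    m
  })
  dimnames(m) <- list(names(diseaseCluster), names(lncCluster))
  list(interaction = new("InteractionMatrix", assoc = m), lncCluster = lncCluster)
}

#' Generate a complete synthetic benchmark bundle
#'
#' Hierarchy plus planted association matrix plus ground-truth clusters;
#' fully determined by the spec (and its seed).
#'
#' @param spec a [syntheticSpec()].
#' @return a \linkS4class{SyntheticBundle}.
#' @examples
#' b <- generateBundle(syntheticSpec(nDiseases = 12, nLncrnas = 20,
#'                                   nClusters = 4))
#' b
#' @export
generateBundle <- function(spec = syntheticSpec()) {
  h <- generateHierarchy(spec)
  a <- generatePlantedAssociations(spec, h$diseaseCluster)
  new("SyntheticBundle", hierarchy = h$hierarchy, interaction = a$interaction,
      diseaseCluster = h$diseaseCluster, lncCluster = a$lncCluster,
      spec = unclass(spec))
}

#' Write a synthetic bundle as the standard TSV trio
#'
#' Association pair list, hierarchy file and interaction matrix, in the
#' formats the readers of this package consume.
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- as.matrix(bundle@interaction)
  ones <- which(m == 1, arr.ind = TRUE)
  paths <- c(pairs = file.path(dir, "pairs.tsv"),
             hierarchy = file.path(dir, "hierarchy.tsv"),
             interaction = file.path(dir, "interaction.tsv"),
             clusters = file.path(dir, "clusters.tsv"))
  writeLines(paste(colnames(m)[ones[, 2]], rownames(m)[ones[, 1]], sep = "\t"),
             paths["pairs"])
  rec <- bundle@hierarchy@records
  writeLines(unlist(lapply(names(rec), function(d) paste(d, rec[[d]], sep = "\t"))),
             paths["hierarchy"])
  writeMatrixTSV(m, paths["interaction"])
  writeLines(c("entity\tcluster",
               paste(names(bundle@diseaseCluster), bundle@diseaseCluster, sep = "\t"),
               paste(names(bundle@lncCluster), bundle@lncCluster, sep = "\t")),
             paths["clusters"])
  invisible(paths)
}
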