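# Seeded synthetic-fixture generators. Every generator is a pure function of
# its FixtureSpec (including the seed), writes plain-text files, and emits a
# ground-truth file sufficient to score downstream results without any
# external data.

#' Construct a fixture specification
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's validation: a compound library with planted similarity clusters
#' standing in for drug classes (statin-like, fibrate-like, ...), a protein
#' universe with a random interaction graph, ontologies with one planted
#' enriched category wired to the first cluster's target block, and an
#' expression study with 5 samples per group and 20 genes planted at 4-fold
#' (2 log2) with 0.25 log2-scale noise.
#'
#' @param seed integer RNG seed; the spec is deterministic given it.
#' @param n_compounds database compounds across all clusters.
#' @param n_clusters number of similarity clusters.
#' @param cluster_tightness required within-cluster Tanimoto lower bound.
#' @param n_proteins protein universe size.
#' @param graph_degree expected degree of the interaction graph.
#' @param n_categories ontology categories.
#' @param planted_category name of the planted category (or \code{NULL}).
#' @param n_genes genes in the expression matrix.
#' @param n_samples_per_group samples per treatment/control group.
#' @param planted_deg_count planted differentially expressed genes per drug.
#' @param planted_log2_effect planted absolute log2 effect size.
#' @param noise_sigma gaussian noise standard deviation on the log2 scale.
#' @param block_size target-block size per cluster.
#' @return validated list of class \code{"FixtureSpec"}.
#' @export
fixtureSpec <- function(seed = 17L, n_compounds = 60L, n_clusters = 3L,
                        cluster_tightness = 0.7, n_proteins = 300L,
                        graph_degree = 4, n_categories = 25L,
                        planted_category = "GS_planted", n_genes = 200L,
                        n_samples_per_group = 5L, planted_deg_count = 20L,
                        planted_log2_effect = 2, noise_sigma = 0.25,
                        block_size = 12L) {
  spec <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
               n_clusters = as.integer(n_clusters),
               cluster_tightness = cluster_tightness,
               n_proteins = as.integer(n_proteins), graph_degree = graph_degree,
               n_categories = as.integer(n_categories),
               planted_category = planted_category,
               n_genes = as.integer(n_genes),
               n_samples_per_group = as.integer(n_samples_per_group),
               planted_deg_count = as.integer(planted_deg_count),
               planted_log2_effect = planted_log2_effect,
               noise_sigma = noise_sigma, block_size = as.integer(block_size))
  counts <- c("n_compounds", "n_clusters", "n_proteins", "n_categories",
              "n_genes", "n_samples_per_group", "block_size")
  for (nm in counts) if (spec[[nm]] < 1L)
    stop(nm, " must be positive", call. = FALSE)
  if (spec$cluster_tightness <= 0 || spec$cluster_tightness >= 1)
    stop("cluster_tightness must lie in (0, 1)", call. = FALSE)
  if (spec$graph_degree < 0) stop("graph_degree must be >= 0", call. = FALSE)
  if (spec$noise_sigma <= 0) stop("noise_sigma must be positive", call. = FALSE)
  if (spec$planted_deg_count < 0 || spec$planted_deg_count > spec$n_genes)
    stop("planted_deg_count must lie in [0, n_genes]", call. = FALSE)
  if (spec$n_clusters * spec$block_size > spec$n_proteins)
    stop("protein universe too small for the requested target blocks",
         call. = FALSE)
  class(spec) <- "FixtureSpec"
  spec
}

.proteinIds <- function(n) sprintf("P%04d", seq_len(n))

# scaffold grid: ring A + linker + ring B; clusters take maximally spread
# combinations so between-cluster similarity stays low
.clusterScaffolds <- function(n_clusters) {
  ringsA <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "c1ccsc1", "c1ccoc1")
  linkers <- c("CC(=O)OC", "CC(=O)NC", "CCOC", "CSC", "C(=O)C")
  ringsB <- c("c1ccccc1", "C1CCCC1", "c1ccc(F)cc1", "c1cncnc1", "C1CCOC1")
  tails <- c("CCOCC", "CCC(=O)C", "CCSC", "CCNCC", "CCCOC")
  if (n_clusters > length(ringsA))
    stop("at most ", length(ringsA), " clusters supported", call. = FALSE)
  vapply(seq_len(n_clusters), function(j)
    paste0(ringsA[j], linkers[j], ringsB[j], tails[j]), "")
}

.decorations <- c("", "C", "CC", "O", "CO", "N", "F", "Cl", "OC", "CN",
                  "C(C)C", "CCC", "CCO", "CF", "CCl", "C(C)O", "CCN", "COC",
                  "Br", "CBr", "C(F)F", "CC(C)C", "CCF", "OCC")

#' Generate the compound database fixture
#'
#' Builds \code{n_compounds} structures by decorating one scaffold per
#' cluster with small substituents, verifies at generation that all
#' within-cluster pairwise Tanimoto similarities reach
#' \code{cluster_tightness} and all between-cluster similarities stay below
#' 0.5, and assigns each cluster a characteristic, disjoint block of target
#' proteins. Writes \code{structures.smi}, \code{interactions.tsv} and the
#' ground truth \code{truth_compounds.tsv} (compound, cluster) plus
#' \code{truth_blocks.tsv} (cluster, protein).
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory (created if needed).
#' @return invisible list of written paths plus the per-compound cluster map.
#' @export
generateCompoundDb <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 101L)
  scaffolds <- .clusterScaffolds(spec$n_clusters)
  per <- ceiling(spec$n_compounds / spec$n_clusters)
  if (per > length(.decorations))
    stop("infeasible fixture: at most ", length(.decorations),
         " compounds per cluster; lower n_compounds or raise n_clusters",
         call. = FALSE)

  rows <- list()
  for (j in seq_len(spec$n_clusters)) {
    decs <- sample(.decorations, per)
    n_j <- min(per, spec$n_compounds - (j - 1L) * per)
    for (i in seq_len(n_j)) {
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = sprintf("CMP%02d%02d", j, i),
        smiles = paste0(scaffolds[j], decs[i]),
        cluster = j, stringsAsFactors = FALSE)
    }
  }
  cmp <- do.call(rbind, rows)

  # verify the planted similarity structure under the default fingerprint
  fps <- lapply(seq_len(nrow(cmp)), function(i)
    computeFingerprint(parseStructure(cmp$compound_id[i], cmp$smiles[i])))
  simmat <- outer(seq_along(fps), seq_along(fps),
                  Vectorize(function(a, b) tanimoto(fps[[a]], fps[[b]])))
  same <- outer(cmp$cluster, cmp$cluster, "==")
  within_min <- min(simmat[same & upper.tri(simmat)])
  between_max <- if (any(!same)) max(simmat[!same & upper.tri(simmat)]) else 0
  if (within_min < spec$cluster_tightness)
    stop(sprintf(paste0("infeasible cluster_tightness %.2f (achieved %.2f); ",
                        "use larger scaffolds or fewer compounds per cluster"),
                 spec$cluster_tightness, within_min), call. = FALSE)
  if (between_max >= 0.5)
    stop(sprintf("between-cluster similarity %.2f >= 0.5; choose more distinct scaffolds",
                 between_max), call. = FALSE)

  proteins <- .proteinIds(spec$n_proteins)
  blocks <- lapply(seq_len(spec$n_clusters), function(j)
    proteins[((j - 1L) * spec$block_size + 1L):(j * spec$block_size)])

  ia <- list()
  for (i in seq_len(nrow(cmp))) {
    blk <- blocks[[cmp$cluster[i]]]
    ntar <- sample(3:min(6, length(blk)), 1L)
    tars <- sort(sample(blk, ntar))
    ia[[length(ia) + 1L]] <- data.frame(
      compound_id = cmp$compound_id[i], protein_id = tars,
      effect = sample(c("activation", "inhibition", "unspecified"), ntar,
                      replace = TRUE),
      directness = sample(c("direct", "indirect"), ntar, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  ia <- do.call(rbind, ia)

  paths <- list(
    structures = file.path(dir, "structures.smi"),
    interactions = file.path(dir, "interactions.tsv"),
    truth_compounds = file.path(dir, "truth_compounds.tsv"),
    truth_blocks = file.path(dir, "truth_blocks.tsv"))
  writeLines(paste(cmp$smiles, cmp$compound_id, sep = "\t"), paths$structures)
  utils::write.table(ia, paths$interactions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cmp[, c("compound_id", "cluster")], paths$truth_compounds,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cluster = rep(seq_along(blocks), lengths(blocks)),
               protein_id = unlist(blocks)),
    paths$truth_blocks, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, list(clusters = cmp$cluster)))
}

#' Generate a random protein interaction graph fixture
#'
#' Erdos-Renyi graph over the protein universe with edge probability
#' \code{graph_degree / (n_proteins - 1)}; no self-loops; deterministic per
#' seed. Writes a two-column TSV edge list.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory.
#' @return invisible path of the edge file.
#' @export
generateInteractionGraph <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 202L)
  n <- spec$n_proteins
  p <- if (n > 1L) min(1, spec$graph_degree / (n - 1)) else 0
  g <- igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
  igraph::V(g)$name <- .proteinIds(n)
  el <- igraph::as_edgelist(g)
  path <- file.path(dir, "ppi_edges.tsv")
  if (nrow(el)) {
    ord <- order(el[, 1L], el[, 2L])
    writeLines(paste(el[ord, 1L], el[ord, 2L], sep = "\t"), path)
  } else writeLines(character(), path)
  invisible(path)
}

#' Generate an ontology fixture with an optional planted category
#'
#' Random categories over the protein universe; when
#' \code{spec$planted_category} is set, that category's members are drawn
#' entirely from the first cluster's target block, so enrichment of the
#' first cluster's drug is planted by construction through the
#' compound-to-target-to-ontology chain. Writes a GMT file and
#' \code{truth_ontology.tsv}.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory.
#' @param name ontology file base name (default \code{"pathway-maps"}).
#' @return invisible list with the GMT and truth paths.
#' @export
generateOntology <- function(spec, dir, name = "pathway-maps") {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 303L)
  proteins <- .proteinIds(spec$n_proteins)
  cats <- list()
  for (i in seq_len(spec$n_categories)) {
    sz <- sample(8:15, 1L)
    cats[[sprintf("GS%03d", i)]] <- sort(sample(proteins, sz))
  }
  planted <- .plantedCategoryMembers(spec)
  if (length(planted)) cats[[spec$planted_category]] <- planted
  # every protein appears somewhere so the ontology universe is the full set
  missing <- setdiff(proteins, unlist(cats))
  if (length(missing)) cats[["GS_background"]] <- missing
  gmt <- file.path(dir, paste0(name, ".gmt"))
  writeLines(vapply(names(cats), function(nm)
    paste(c(nm, "synthetic", cats[[nm]]), collapse = "\t"), ""), gmt)
  truth <- file.path(dir, "truth_ontology.tsv")
  utils::write.table(
    data.frame(category = if (length(planted)) spec$planted_category else NA,
               protein_id = if (length(planted)) planted else NA),
    truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(gmt = gmt, truth = truth))
}

#' Generate an expression-study fixture with planted DEGs
#'
#' Log-normal baseline intensities (log2 means uniform in [5, 12]) with
#' gaussian log2-scale noise; one control group plus one treatment group per
#' drug, \code{n_samples_per_group} samples each. For each drug,
#' \code{planted_deg_count} genes are shifted by \code{planted_log2_effect}
#' in that drug's group. The first drug's planted set contains the planted
#' ontology category's members (up-regulated), wiring the expression arm to
#' the same ground truth as the structure arm. Writes \code{expression.tsv},
#' \code{design.tsv} and \code{truth_expression.tsv}.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory.
#' @param drugs character vector of drug ids (default \code{"D1".."D3"}).
#' @return invisible list of written paths.
#' @export
generateExpression <- function(spec, dir, drugs = c("D1", "D2", "D3")) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 404L)
  genes <- .proteinIds(spec$n_proteins)[seq_len(spec$n_genes)]
  nper <- spec$n_samples_per_group
  groups <- c("Ctrl", drugs)
  samples <- unlist(lapply(groups, function(g) sprintf("%s_%d", g, seq_len(nper))))
  design <- data.frame(sample = samples,
                       group = rep(groups, each = nper),
                       stringsAsFactors = FALSE)

  base <- stats::runif(spec$n_genes, 5, 12)   # log2 baseline per gene
  planted <- .plantedDegSets(spec, drugs, genes)

  lg <- matrix(rep(base, length(samples)), nrow = spec$n_genes,
               dimnames = list(genes, samples))
  set.seed(spec$seed + 405L)
  for (d in seq_along(drugs)) {
    pd <- planted[[drugs[d]]]
    idx <- match(pd$gene, genes)
    cols <- design$group == drugs[d]
    lg[idx, cols] <- lg[idx, cols] +
      pd$sign * spec$planted_log2_effect
  }
  noise <- matrix(stats::rnorm(length(lg), 0, spec$noise_sigma),
                  nrow = nrow(lg))
  vals <- 2^(lg + noise)

  paths <- list(matrix = file.path(dir, "expression.tsv"),
                design = file.path(dir, "design.tsv"),
                truth = file.path(dir, "truth_expression.tsv"))
  out <- data.frame(gene = genes, round(vals, 4), check.names = FALSE)
  utils::write.table(out, paths$matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(design, paths$design, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- do.call(rbind, lapply(names(planted), function(d)
    data.frame(drug = rep(d, nrow(planted[[d]])), gene = planted[[d]]$gene,
               direction = ifelse(planted[[d]]$sign > 0, "up", "down"),
               stringsAsFactors = FALSE)))
  if (is.null(truth)) truth <- data.frame(drug = character(),
                                          gene = character(),
                                          direction = character())
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

# the planted ontology category's members: a fixed-seed draw from the first
# cluster's target block, shared by the ontology and expression generators
.plantedCategoryMembers <- function(spec) {
  if (is.null(spec$planted_category)) return(character())
  set.seed(spec$seed + 307L)
  block1 <- .proteinIds(spec$n_proteins)[seq_len(spec$block_size)]
  sort(sample(block1, min(8L, length(block1))))
}

# planted DEG sets per drug: drug 1 anchors the planted ontology category
# (up-regulated); remaining slots and drugs are seeded random draws
.plantedDegSets <- function(spec, drugs, genes) {
  anchor <- intersect(.plantedCategoryMembers(spec), genes)
  set.seed(spec$seed + 406L)
  planted <- list()
  for (d in seq_along(drugs)) {
    if (spec$planted_deg_count == 0L) {
      planted[[drugs[d]]] <- data.frame(gene = character(), sign = numeric(),
                                        stringsAsFactors = FALSE)
      next
    }
    if (d == 1L && length(anchor)) {
      extra <- sample(setdiff(genes, anchor),
                      max(0L, spec$planted_deg_count - length(anchor)))
      gs <- c(anchor, extra)
      sgn <- c(rep(1, length(anchor)),
               sample(c(-1, 1), length(extra), replace = TRUE))
    } else {
      gs <- sample(genes, spec$planted_deg_count)
      sgn <- sample(c(-1, 1), length(gs), replace = TRUE)
    }
    ord <- order(gs)
    planted[[drugs[d]]] <- data.frame(gene = gs[ord], sign = sgn[ord],
                                      stringsAsFactors = FALSE)
  }
  planted
}

#' Generate a complete, ready-to-run fixture directory
#'
#' Emits every input the pipeline consumes -- compound database, interaction
#' graph, ontology, expression study, default rule table, query-drug
#' structures and a \code{config.json} -- plus all ground-truth files. The
#' three query drugs realize the planted study design: drugs 1 and 2 are
#' decorated variants of the first similarity cluster's scaffold (a shared
#' drug class), drug 3 comes from the last cluster.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory.
#' @return invisible path of the written config file.
#' @export
generateFixtureRun <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  generateCompoundDb(spec, dir)
  generateInteractionGraph(spec, dir)
  generateOntology(spec, dir)
  drugs <- c("D1", "D2", "D3")
  generateExpression(spec, dir, drugs = drugs)

  scaffolds <- .clusterScaffolds(spec$n_clusters)
  qsmi <- c(paste0(scaffolds[1L], "CO"),
            paste0(scaffolds[1L], "N"),
            paste0(scaffolds[spec$n_clusters], "CO"))
  writeLines(paste(qsmi, drugs, sep = "\t"), file.path(dir, "drugs.smi"))

  rules <- defaultMetabolicRules()
  utils::write.table(rules, file.path(dir, "rules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  config <- list(
    drugs = file.path(dir, "drugs.smi"),
    rules = file.path(dir, "rules.tsv"),
    db = list(structures = file.path(dir, "structures.smi"),
              interactions = file.path(dir, "interactions.tsv")),
    graph = file.path(dir, "ppi_edges.tsv"),
    ontologies = list(file.path(dir, "pathway-maps.gmt")),
    expression = list(
      matrix = file.path(dir, "expression.tsv"),
      design = file.path(dir, "design.tsv"),
      contrasts = lapply(drugs, function(d)
        list(drug = d, treatment = d, control = "Ctrl"))),
    seed = spec$seed)
  cfg <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg, auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg)
}
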