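#' Generate a planted-module miRNA-disease benchmark dataset
#'
#' Builds a fully self-contained dataset with known ground truth: miRNAs and
#' diseases are split into contiguous, near-equal modules; miRNA module `c`
#' is matched one-to-one to disease module `c` (cyclically when the counts
#' differ); an association is drawn with probability `p_in` between matched
#' modules and `p_out` otherwise. A term hierarchy makes same-module
#' diseases siblings under a shared branch node (block-structured semantic
#' similarity), and gene evidence gives same-module diseases heavily
#' overlapping gene sets drawn from a module-specific pool whose internal
#' gene-gene similarities are high. Regenerating with the same seed
#' reproduces every field bitwise.
#'
#' @param n_m,n_d numbers of miRNAs and diseases.
#' @param k_true_m,k_true_d numbers of planted miRNA / disease modules.
#' @param p_in association probability between matched modules.
#' @param p_out association probability otherwise; must satisfy
#'   `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @param genes_per_module,genes_per_disease sizes of the per-module gene
#'   pool and of each disease's draw from it.
#' @param within_gene_sim gene-gene similarity assigned inside a module's
#'   gene pool.
#' @return An object of class `synthetic_dataset`: list with `assoc`,
#'   `true_mirna_modules`, `true_disease_modules`, `module_link`
#'   (module-pair association probabilities), `disease_genes`, `gene_sim`,
#'   `dag`, `seed`.
#' @export
generate_planted <- function(n_m = 60, n_d = 40, k_true_m = 4, k_true_d = 4,
                             p_in = 0.6, p_out = 0.02, seed = 0,
                             genes_per_module = 8, genes_per_disease = 5,
                             within_gene_sim = 0.9) {
  stopifnot(k_true_m <= n_m, k_true_d <= n_d,
            p_out >= 0, p_in <= 1, p_out <= p_in)
  mir <- sprintf("m%03d", seq_len(n_m))
  dis <- sprintf("d%03d", seq_len(n_d))
  mod_m <- stats::setNames(as.integer(cut(seq_len(n_m), k_true_m)), mir)
  mod_d <- stats::setNames(as.integer(cut(seq_len(n_d), k_true_d)), dis)
  match_d <- ((seq_len(k_true_m) - 1) %% k_true_d) + 1L
  link <- matrix(p_out, k_true_m, k_true_d)
  link[cbind(seq_len(k_true_m), match_d)] <- p_in
  P <- link[mod_m, mod_d]
  with_seed(seed, {
    D <- matrix(as.numeric(stats::runif(n_m * n_d) < P), n_m, n_d,
                dimnames = list(mir, dis))
    pools <- lapply(seq_len(k_true_d), function(c)
      sprintf("g%d_%02d", c, seq_len(genes_per_module)))
    disease_genes <- lapply(dis, function(d)
      sample(pools[[mod_d[d]]], genes_per_disease))
    names(disease_genes) <- dis
    gene_sim <- do.call(rbind, lapply(pools, function(pool) {
      idx <- utils::combn(pool, 2)
      data.frame(a = idx[1, ], b = idx[2, ], w = within_gene_sim,
                 stringsAsFactors = FALSE)
    }))
    branches <- sprintf("branch%d", seq_len(k_true_d))
    edges <- rbind(cbind(dis, branches[mod_d]),
                   cbind(branches, "root"))
    dag <- disease_dag(edges)
    structure(
      list(assoc = association_data(D),
           true_mirna_modules = mod_m, true_disease_modules = mod_d,
           module_link = link, disease_genes = disease_genes,
           gene_sim = weighted_pairs(gene_sim), dag = dag, seed = seed),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d x %d, %d/%d planted modules, %d positives, seed %d\n",
    length(x$assoc$mirna), length(x$assoc$disease),
    max(x$true_mirna_modules), max(x$true_disease_modules),
    sum(x$assoc$D == 1), x$seed))
  invisible(x)
}

#' Fixed toy disease hierarchy: a chain with siblings
#'
#' Four terms: root `r`, its child `p`, and two siblings `d` and `e` under
#' `p`. Small enough that semantic profiles and similarities can be checked
#' by hand (with contribution factor 0.5, `d`'s profile is
#' `{d: 1, p: 0.5, r: 0.25}` and the sibling similarity is 3/7).
#'
#' @return A [disease_dag()] with 4 nodes and 3 edges.
#' @export
toy_dag_chain_and_siblings <- function() {
  disease_dag(rbind(c("p", "r"), c("d", "p"), c("e", "p")))
}

#' Write a synthetic dataset's input files
#'
#' Emits the four raw input tables in the package's TSV dialects:
#' `associations.tsv` (mirna, disease), `dag_edges.tsv` (child, parent),
#' `gene_similarity.tsv` (gene_a, gene_b, weight) and
#' `disease_genes.tsv` (disease, gene).
#'
#' @param ds a [generate_planted()] result.
#' @param dir output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(association = file.path(dir, "associations.tsv"),
             dag = file.path(dir, "dag_edges.tsv"),
             gene_sim = file.path(dir, "gene_similarity.tsv"),
             disease_genes = file.path(dir, "disease_genes.tsv"))
  pos <- which(ds$assoc$D == 1, arr.ind = TRUE)
  utils::write.table(
    data.frame(mirna = ds$assoc$mirna[pos[, 1]],
               disease = ds$assoc$disease[pos[, 2]]),
    paths["association"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$dag$edges, paths["dag"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$gene_sim, paths["gene_sim"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  dg <- data.frame(
    disease = rep(names(ds$disease_genes), lengths(ds$disease_genes)),
    gene = unlist(ds$disease_genes, use.names = FALSE))
  utils::write.table(dg, paths["disease_genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
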