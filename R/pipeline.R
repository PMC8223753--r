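#' Configuration for an end-to-end prediction run
#'
#' @param association path to the miRNA-disease association TSV.
#' @param dag_edges path to the disease hierarchy edge TSV.
#' @param gene_sim path to the gene-gene similarity TSV.
#' @param disease_genes path to the disease-gene TSV.
#' @param out_dir output directory.
#' @param hp an [mdn_hyperparams()] list.
#' @param method `"nmtf"` (reconstruction scores only) or `"nmtf2"`
#'   (adds module extraction, propagation and fusion).
#' @param t module threshold multiplier.
#' @param delta semantic contribution factor.
#' @param top_k candidates per disease in the ranked prediction table.
#' @return A list of class `run_config`.
#' @export
run_config <- function(association, dag_edges, gene_sim, disease_genes,
                       out_dir, hp = mdn_hyperparams(),
                       method = c("nmtf2", "nmtf"), t = 1.5, delta = 0.5,
                       top_k = 50) {
  method <- match.arg(method)
  paths <- c(association = unname(association), dag_edges = unname(dag_edges),
             gene_sim = unname(gene_sim), disease_genes = unname(disease_genes))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  structure(list(paths = paths, out_dir = out_dir, hp = hp, method = method,
                 t = t, delta = delta, top_k = top_k),
            class = "run_config")
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full prediction pipeline
#'
#' Reads the four raw inputs, builds the integrated similarity networks,
#' fits the tri-factorization model and writes the reconstruction scores
#' `D1`. With `method = "nmtf2"` it additionally extracts soft miRNA and
#' disease modules from the learned factors, propagates the known
#' associations through them and writes the fused scores `D2` plus the two
#' module tables. Always persists the objective trace, a ranked prediction
#' table (training positives excluded) and a machine-readable run manifest
#' with the seed, parameters and MD5 checksums of inputs and outputs, so a
#' rerun can be verified to be bitwise identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `fit`, `D1`, `D2` (or `NULL`),
#'   `modules_m`, `modules_d` (or `NULL`) and the `manifest`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  assoc <- stage("read_inputs", read_association_table(config$paths["association"]))
  dag <- stage("read_inputs", read_dag_edges(config$paths["dag_edges"],
                                             nodes = assoc$disease))
  gene_sim <- stage("read_inputs", read_weighted_pairs(config$paths["gene_sim"]))
  disease_genes <- stage("read_inputs",
                         read_disease_genes(config$paths["disease_genes"]))
  sims <- stage("similarity",
                compute_similarities(assoc, dag, disease_genes, gene_sim,
                                     delta = config$delta))
  fit <- stage("factorization", mdn_fit(sims$Rm, sims$Rd, assoc, config$hp))
  D1 <- stage("prediction", predict_scores(fit))
  out <- list(fit = fit, D1 = D1, D2 = NULL,
              modules_m = NULL, modules_d = NULL)
  files <- c(D1 = file.path(config$out_dir, "D1.tsv"))
  write_matrix_tsv(D1, files["D1"])
  trace_path <- file.path(config$out_dir, "objective_trace.tsv")
  utils::write.table(
    data.frame(iteration = seq_along(fit$objective_trace) - 1L,
               objective = fit$objective_trace),
    trace_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files["objective_trace"] <- trace_path
  final_scores <- D1
  if (config$method == "nmtf2") {
    out$modules_m <- stage("modules", assign_modules(fit$Gm, config$t))
    out$modules_d <- stage("modules", assign_modules(fit$Gd, config$t))
    Pm <- stage("module_scores",
                module_score_mirna(out$modules_m, fit$Gm, assoc$D))
    Pd <- stage("module_scores",
                module_score_disease(out$modules_d, fit$Gd, assoc$D))
    out$D2 <- stage("fusion", fuse_predictions(D1, Pm, Pd))
    files["D2"] <- file.path(config$out_dir, "D2.tsv")
    write_matrix_tsv(out$D2, files["D2"])
    files["modules_mirna"] <- file.path(config$out_dir, "modules_mirna.tsv")
    files["modules_disease"] <- file.path(config$out_dir, "modules_disease.tsv")
    write_module_table(out$modules_m, fit$Gm, files["modules_mirna"])
    write_module_table(out$modules_d, fit$Gd, files["modules_disease"])
    final_scores <- out$D2
  }
  files["predictions"] <- file.path(config$out_dir, "predictions.tsv")
  stage("report", write_predictions(final_scores, files["predictions"],
                                    config$top_k,
                                    exclude = assoc$D == 1 & assoc$known))
  manifest <- list(
    method = config$method,
    seed = config$hp$seed,
    hyperparams = unclass(config$hp),
    t = config$t, delta = config$delta, top_k = config$top_k,
    input_md5 = as.list(tools::md5sum(unname(config$paths))),
    output_md5 = as.list(tools::md5sum(unname(files)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
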