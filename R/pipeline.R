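# End-to-end orchestration: simulate -> phenotype -> quantgen -> GWAS ->
# splicing -> differential expression, with provenance-stamped TSV outputs
# and report tables.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every stage's generator seed derives from it.
#' @param stages Stages to run, a subset of
#'   `c("phenotype", "quantgen", "gwas", "splicing", "diffexpr")`.
#' @param maf_threshold,gwas_alpha,fdr_alpha,dpsi_floor,fc_gate Analysis
#'   thresholds.
#' @param activity_cfg,panel_cfg,splicing_cfg,expr_cfg Optional simulator
#'   configurations (defaults are built from `seed`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("flysih_run_"), seed = 1,
                            stages = c("phenotype", "quantgen", "gwas",
                                       "splicing", "diffexpr"),
                            maf_threshold = 0.05, gwas_alpha = 1e-5,
                            fdr_alpha = 0.05, dpsi_floor = 0.10,
                            fc_gate = 2, activity_cfg = NULL,
                            panel_cfg = NULL, splicing_cfg = NULL,
                            expr_cfg = NULL) {
  stopifnot(maf_threshold >= 0, maf_threshold < 0.5,
            gwas_alpha > 0, gwas_alpha < 1, fdr_alpha > 0, fdr_alpha < 1,
            dpsi_floor >= 0, dpsi_floor < 1, fc_gate >= 1)
  if (is.null(activity_cfg)) activity_cfg <- activity_sim_config(seed = seed)
  if (is.null(panel_cfg)) panel_cfg <- panel_sim_config(seed = seed + 1)
  if (is.null(splicing_cfg)) splicing_cfg <- splicing_sim_config(seed = seed + 2)
  if (is.null(expr_cfg)) expr_cfg <- expr_sim_config(seed = seed + 3)
  structure(as.list(environment()), class = "pipeline_config")
}

fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_stage_tsv <- function(df, path, seed, cfg_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flysih %s | seed=%d | config=%s",
                     as.character(utils::packageVersion("flysih")),
                     seed, cfg_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on simulated inputs
#'
#' Executes the requested stages in dependency order on inputs drawn from
#' the configured generators, writing one provenance-stamped TSV per output
#' and returning a manifest of outputs and summary statistics. The same
#' configuration (including seed) reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_manifest` list with `outputs` (named file paths),
#'   `summary` (named numbers) and `config`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- fnv1a_hash(config[setdiff(names(config), "out_dir")])
  outputs <- list()
  summary <- list()
  emit <- function(df, name) {
    outputs[[name]] <<- write_stage_tsv(
      df, file.path(config$out_dir, paste0(name, ".tsv")),
      config$seed, hash)
  }
  phen <- NULL
  fly_das <- NULL
  if (any(c("phenotype", "quantgen") %in% config$stages)) {
    sim <- simulate_activity(config$activity_cfg)
    at <- to_activity_table(sim$monitors, sim$layout, sim$origin)
    ws <- window_sums(at)
    fly_das <- delta_activity(ws)
    phen <- strain_phenotypes(at)
    emit(phen, "strain_phenotypes")
    summary$n_strains <- nrow(phen)
    summary$max_strain_da <- max(phen$da_mean)
  }
  if ("quantgen" %in% config$stages) {
    vc <- variance_components(fly_das$strain_id, fly_das$da)
    ct_sr <- pearson_test(phen$da_mean, phen$sr)
    ct_base <- pearson_test(phen$da_mean, phen$baseline)
    qg <- data.frame(
      quantity = c("H2", "sigma2_G", "sigma2_E", "rho_da_sr", "p_da_sr",
                   "rho_da_baseline", "p_da_baseline"),
      value = c(vc$H2, vc$sigma2_g, vc$sigma2_e, ct_sr$rho, ct_sr$p_value,
                ct_base$rho, ct_base$p_value))
    emit(qg, "quantgen")
    summary$H2 <- vc$H2
    summary$rho_da_sr <- ct_sr$rho
  }
  if ("gwas" %in% config$stages) {
    sim <- simulate_panel(config$panel_cfg)
    line_means <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
    y <- adjust_covariates(line_means[sim$panel$lines], sim$covariates)
    panel <- maf_filter(sim$panel, config$maf_threshold)
    K <- compute_grm(panel)
    scan <- association_scan(y, panel, K)
    hits <- significant_hits(scan, config$gwas_alpha)
    emit(scan, "association_scan")
    emit(hits, "significant_hits")
    summary$n_variants_scanned <- sum(!is.na(scan$p_value))
    summary$n_hits <- nrow(hits)
    summary$lambda_gc <- lambda_gc(scan$p_value)
  }
  if ("splicing" %in% config$stages) {
    sim <- simulate_junctions(config$splicing_cfg)
    ds <- differential_splicing(sim$junctions, sim$counts, sim$condition,
                                fdr_alpha = config$fdr_alpha,
                                dpsi_floor = config$dpsi_floor)
    emit(ds$clusters, "splicing_clusters")
    emit(ds$introns, "splicing_introns")
    sig <- ds$clusters[ds$clusters$significant &
                         ds$clusters$magnitude_class != "below-threshold", ]
    summary$n_sig_clusters <- sum(ds$clusters$significant)
    summary$pct_small <- round(100 * mean(sig$magnitude_class == "small"), 1)
  }
  if ("diffexpr" %in% config$stages) {
    sim <- simulate_expression(config$expr_cfg)
    de <- de_filter(nb_test(sim$counts, sim$condition),
                    fdr_alpha = config$fdr_alpha, fc_gate = config$fc_gate)
    emit(de, "differential_expression")
    summary$n_up <- attr(de, "n_up")
    summary$n_down <- attr(de, "n_down")
  }
  manifest <- structure(list(outputs = outputs,
                             summary = unlist(summary),
                             config = config, hash = hash),
                        class = "pipeline_manifest")
  emit(data.frame(key = names(manifest$summary),
                  value = unname(manifest$summary)), "summary")
  manifest$outputs <- outputs
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("flysih pipeline run (config", x$hash, ")\n")
  cat("outputs:\n")
  for (nm in names(x$outputs)) cat("  -", x$outputs[[nm]], "\n")
  cat("summary:\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Build report tables from a pipeline run
#'
#' Produces analysis-ready tables: the strain DA ranking, Manhattan and QQ
#' tables for the association scan, the grouped site-class distribution
#' (when site classes are available), and the splicing magnitude-class
#' table. Sections for stages that did not run are omitted with a note.
#'
#' @param manifest A `pipeline_manifest` from [run_pipeline()].
#' @param association Optional association table with a `site_class`
#'   column for the site-distribution section (e.g. [dgrp_sih_hits()]).
#' @return Named list of data frames; a `notes` element lists omitted
#'   sections.
#' @export
make_report <- function(manifest, association = NULL) {
  read_out <- function(name) {
    p <- manifest$outputs[[name]]
    if (is.null(p) || !file.exists(p)) return(NULL)
    utils::read.delim(p, comment.char = "#", stringsAsFactors = FALSE)
  }
  report <- list()
  notes <- character(0)
  phen <- read_out("strain_phenotypes")
  if (!is.null(phen)) {
    report$strain_ranking <- phen[order(phen$da_mean), ]
  } else notes <- c(notes, "phenotype stage missing: ranking omitted")
  scan <- read_out("association_scan")
  if (!is.null(scan)) {
    report$manhattan <- scan[, c("chrom", "pos", "variant_id", "p_value")]
    p <- sort(scan$p_value[!is.na(scan$p_value)])
    report$qq <- data.frame(
      expected = -log10(stats::ppoints(length(p))),
      observed = -log10(p))
  } else notes <- c(notes, "gwas stage missing: manhattan/qq omitted")
  if (!is.null(association) && "site_class" %in% names(association)) {
    sd <- summarize_site_distribution(association$site_class)
    report$site_distribution <- data.frame(group = names(sd),
                                           percent = unname(sd))
  } else notes <- c(notes, "no classified association records: site distribution omitted")
  clus <- read_out("splicing_clusters")
  if (!is.null(clus)) {
    sig <- clus[clus$significant == "TRUE" | clus$significant == TRUE, ]
    sig <- sig[sig$magnitude_class != "below-threshold", ]
    tab <- table(factor(sig$magnitude_class,
                        levels = c("small", "intermediate", "large")))
    report$splicing_classes <- data.frame(
      class = names(tab), n = as.integer(tab),
      percent = round(100 * as.integer(tab) / max(1, sum(tab)), 1))
  } else notes <- c(notes, "splicing stage missing: class table omitted")
  report$notes <- notes
  report
}
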