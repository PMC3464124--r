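# End-to-end orchestration: ultrametricize -> delimit -> reduce -> dec ->
# divtest, with JSON-first reporting. External Bayesian dating is a
# pass-through: supply a dated chronogram for the biogeography and
# diversification stages.

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing per-stage TSV/JSON artifacts
#' under `config$out_dir` plus a combined JSON report that embeds the seed, the
#' package version, and a hash of the configuration. A stage failure stops the
#' run with a stage-attributed error. Input files are never modified.
#'
#' Recognized config fields (all paths relative to the working directory):
#' `tree` (newick/NEXUS phylogram for `ultrametricize`/`delimit`), `chronogram`
#' (dated tree for `dec`/`divtest`), `outgroups` (labels pruned before
#' diversification analyses), `alignment` (FASTA for `reduce`), `dec_config`
#' (YAML/JSON for the stratified model), `tip_ranges` (TSV), `root_age`,
#' `mccr` (list: `n_total`, `replicates`), `shift_times` (ages to test),
#' `epsilon` (for net-diversification rates), `seed`, `out_dir`, `stages`.
#'
#' @param config Named list (or path to a YAML file) of settings.
#' @return The report list, invisibly; also written as `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("ultrametricize", "delimit", "divtest")
  out_dir <- config$out_dir %||% "museumdiv_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  report <- list(package = "museumdiv",
                 version = as.character(utils::packageVersion("museumdiv")),
                 seed = seed,
                 config_hash = config_hash(config),
                 stages = list())
  state <- list()
  for (st in stages) {
    res <- tryCatch(
      switch(st,
             ultrametricize = stage_ultrametricize(config, state, out_dir),
             delimit = stage_delimit(config, state, out_dir),
             reduce = stage_reduce(config, state, out_dir),
             dec = stage_dec(config, state, out_dir),
             divtest = stage_divtest(config, state, out_dir),
             stop("unknown stage: ", st)),
      error = function(e) stop("stage '", st, "' failed: ", conditionMessage(e),
                               call. = FALSE))
    state <- res$state
    report$stages[[st]] <- res$report
    message("stage '", st, "' done")
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)
  unname(tools::md5sum(tf))
}

stage_ultrametricize <- function(config, state, out_dir) {
  tree <- parse_tree(config$tree)
  res <- mpl_ultrametricize(tree, root_age = config$root_age %||% 1)
  ct <- try(clock_test(tree), silent = TRUE)
  write_tree(res$chronogram, file.path(out_dir, "chronogram.nwk"))
  if (!inherits(ct, "try-error"))
    write_tsv_report(as.data.frame(ct), file.path(out_dir, "clock_test.tsv"))
  state$chronogram <- res$chronogram
  list(state = state,
       report = list(n_tips = ape::Ntip(res$chronogram),
                     root_age = res$root_age,
                     clock_rejected = if (inherits(ct, "try-error")) NA
                     else attr(ct, "rejected")))
}

stage_delimit <- function(config, state, out_dir) {
  tree <- state$chronogram %||% parse_tree(config$chronogram %||% config$tree)
  if (!is_ultrametric_tree(tree, 1e-3))
    stop("GMYC needs an ultrametric tree; run the 'ultrametricize' stage ",
         "first or supply a chronogram")
  if (!is_ultrametric_tree(tree)) tree <- snap_ultrametric(tree)
  fit <- gmyc_fit(tree)
  utils::write.table(fit$clusters, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gj <- list(threshold = fit$threshold, n_entities = fit$n_entities,
             logL_gmyc = fit$logL_gmyc, logL_null = fit$logL_null,
             LR = fit$LR, df = fit$df, p = fit$p,
             entity_range = fit$confidence$entity_range)
  jsonlite::write_json(gj, file.path(out_dir, "gmyc.json"),
                       auto_unbox = TRUE, digits = NA)
  state$gmyc <- fit
  list(state = state, report = gj)
}

stage_reduce <- function(config, state, out_dir) {
  if (is.null(state$gmyc)) stop("'reduce' needs the 'delimit' stage first")
  aln <- read_fasta(config$alignment)
  cons <- consensus_reduce(aln, state$gmyc$clusters)
  write_fasta(cons, file.path(out_dir, "consensus.fasta"))
  state$consensus <- cons
  list(state = state, report = list(n_sequences = length(cons)))
}

stage_dec <- function(config, state, out_dir) {
  tree <- parse_tree(config$chronogram)
  cfg <- read_dec_config(config$dec_config)
  ranges <- read_tip_ranges(config$tip_ranges, cfg$space)
  fit <- dec_optimize(tree, ranges, cfg$model, cfg$space,
                      root_range = cfg$root_range)
  utils::write.table(fit$nodes, file.path(out_dir, "dec_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dj <- list(d = fit$d, e = fit$e, lnL = fit$lnL)
  jsonlite::write_json(dj, file.path(out_dir, "dec.json"),
                       auto_unbox = TRUE, digits = NA)
  state$dec <- fit
  list(state = state, report = dj)
}

stage_divtest <- function(config, state, out_dir) {
  tree <- if (!is.null(config$chronogram)) parse_tree(config$chronogram)
  else state$chronogram %||% parse_tree(config$tree)
  if (!is.null(config$outgroups))
    tree <- prune_tips(tree, intersect(config$outgroups, tree$tip.label))
  if (!is_ultrametric_tree(tree)) tree <- snap_ultrametric(tree)
  bt <- branching_times(tree)
  gs <- gamma_stat(bt)
  rep <- list(n_tips = bt$n_tips, crown_age = bt$ages[1L],
              gamma = gs$gamma, gamma_p = gs$p_one_tailed)
  if (!is.null(config$mccr)) {
    mc <- mccr_test(gs$gamma, config$mccr$n_total, bt$n_tips,
                    replicates = config$mccr$replicates %||% 10000L)
    rep$mccr <- list(critical_value = mc$critical_value, p = mc$p,
                     n_total = mc$n_total, replicates = mc$replicates)
  }
  fits <- c(fit_rate_constant(bt), fit_rate_variable(bt))
  rep$models <- lapply(fits, function(f)
    list(k = f$k, lnL = f$lnL, AIC = f$AIC, params = f$params))
  da <- delta_aic_rc(fits)
  rep$delta_aic_rc <- da$delta_aic_rc
  rep$LR <- da$LR
  rep$LR_p <- da$p
  if (!is.null(config$shift_times)) {
    rep$shift_tests <- lapply(config$shift_times, function(tau) {
      s <- try(shift_at_time_test(bt, tau), silent = TRUE)
      if (inherits(s, "try-error")) list(tau = tau, error = TRUE)
      else list(tau = tau, lambda_before = s$lambda_before,
                lambda_after = s$lambda_after, LR = s$LR, p = s$p)
    })
  }
  rc <- rel_cladogenesis_test(tree)
  utils::write.table(rc, file.path(out_dir, "rel_cladogenesis.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rep$rel_clad_significant <- sum(rc$significant)
  nd <- ms_netdiv(bt$n_tips, t_crown = bt$ages[1L],
                  epsilon = config$epsilon %||% c(0, 0.5, 0.9))
  rep$net_diversification <- nd
  write_tsv_report(bt, file.path(out_dir, "branching_times.tsv"))
  write_tsv_report(ltt_curve(bt), file.path(out_dir, "ltt.tsv"))
  jsonlite::write_json(rep, file.path(out_dir, "divtest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state$divtest <- rep
  list(state = state, report = rep)
}

#' Default shift-test event ages
#'
#' Editable defaults for the major paleoclimatic events usually probed in
#' Neotropical diversification studies: the Eocene-Oligocene glacial maximum
#' (EOGM, 34 Ma), the late Oligocene warming event (LOWE, 25 Ma), the
#' mid-Miocene climatic optimum (MMCO, 15 Ma), and the onset of Pleistocene
#' glaciations (PPG, 2.6 Ma).
#'
#' @return Named numeric vector of ages (Ma).
#' @export
default_event_times <- function() {
  c(EOGM = 34, LOWE = 25, MMCO = 15, PPG = 2.6)
}
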