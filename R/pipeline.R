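#' Run the full pan-miRNome pipeline on a synthetic panel
#'
#' End-to-end orchestration: panel synthesis, per-lineage miRNA
#' discovery, pan-genome presence/conservation analysis, repeat
#' classification, target prediction, and the downstream network
#' analytics (clustering, multiplicity, teams). Each stage writes its
#' outputs under `out_dir`; a JSON summary ties them together. Re-runs
#' are idempotent: a stage whose outputs already exist is skipped (its
#' results are reloaded from disk when a later stage needs them) unless
#' `force = TRUE`. A stage whose prerequisite stage never ran aborts
#' with a stage-tagged dependency error.
#'
#' @param out_dir output directory.
#' @param config panel configuration from [default_panel_config()].
#' @param stages character vector of stages to run, a subset of
#'   `c("synth", "discover", "pangenome", "repeats", "targets",
#'   "networks")` in that order.
#' @param force re-run stages whose outputs already exist.
#' @param engine folding engine for discovery and UPE, see [fold()].
#' @param expectation_max,upe_max target-filter cutoffs.
#' @param identity clustering identity threshold.
#' @return the summary list, invisibly. Side effect: files under
#'   `out_dir` (`panel/`, `discovery/`, `pangenome/`, `repeats/`,
#'   `targets/`, `networks/`, `summary.json`, `config.yaml`).
#' @export
run_pipeline <- function(out_dir,
                         config = default_panel_config(),
                         stages = c("synth", "discover", "pangenome",
                                    "repeats", "targets", "networks"),
                         force = FALSE,
                         engine = c("fallback", "thermo"),
                         expectation_max = 3, upe_max = 25,
                         identity = 0.90) {
  engine <- match.arg(engine)
  all_stages <- c("synth", "discover", "pangenome", "repeats", "targets",
                  "networks")
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  if (!file.exists(cfg_path) || force) {
    yaml::write_yaml(list(stages = stages, engine = engine,
                          expectation_max = expectation_max,
                          upe_max = upe_max, identity = identity,
                          panel = config), cfg_path)
  }

  panel_dir <- file.path(out_dir, "panel")
  disc_dir <- file.path(out_dir, "discovery")
  pan_dir <- file.path(out_dir, "pangenome")
  rep_dir <- file.path(out_dir, "repeats")
  tgt_dir <- file.path(out_dir, "targets")
  net_dir <- file.path(out_dir, "networks")
  loci_path <- file.path(disc_dir, "loci.tsv")
  rep_path <- file.path(rep_dir, "loci_repeats.tsv")
  hits_path <- file.path(tgt_dir, "hits.tsv")

  state <- new.env(parent = emptyenv())
  safe_name <- function(lin) gsub("[^A-Za-z0-9_.-]", "_", lin)
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("dependency error: this stage requires outputs of the '",
           stage, "' stage; enable it or run it first", call. = FALSE)
    }
    path
  }
  get_panel <- function() {
    if (is.null(state$panel)) {
      need(file.path(panel_dir, "truth.json"), "synth")
      state$panel <- generate_panel(config)  # deterministic from config
    }
    state$panel
  }
  get_loci <- function() {
    if (is.null(state$loci)) {
      state$loci <- utils::read.delim(need(loci_path, "discover"),
                                      stringsAsFactors = FALSE)
    }
    state$loci
  }
  get_hits <- function() {
    if (is.null(state$hits)) {
      state$hits <- utils::read.delim(need(hits_path, "targets"),
                                      stringsAsFactors = FALSE)
    }
    state$hits
  }
  get_pm <- function() {
    if (is.null(state$pm)) {
      df <- utils::read.delim(need(file.path(pan_dir, "presence.tsv"),
                                   "pangenome"),
                              stringsAsFactors = FALSE, check.names = FALSE)
      sets <- lapply(stats::setNames(names(df)[-1], names(df)[-1]),
                     function(l) df$family[df[[l]] == 1])
      state$pm <- build_presence_matrix(sets)
    }
    state$pm
  }
  get_cds <- function() {
    if (is.null(state$cds)) {
      need(file.path(panel_dir, "truth.json"), "synth")
      state$cds <- lapply(stats::setNames(config$lineage_names,
                                          config$lineage_names),
                          function(lin) {
        ss <- read_genome(file.path(panel_dir, "cds",
                                    paste0(safe_name(lin), ".fa")))
        stats::setNames(as.character(ss), names(ss))
      })
    }
    state$cds
  }

  # ---- synth ------------------------------------------------------------
  if ("synth" %in% stages &&
      (force || !file.exists(file.path(panel_dir, "truth.json")))) {
    panel <- generate_panel(config)
    write_panel(panel, panel_dir)
    state$panel <- panel
  }

  # ---- discover ---------------------------------------------------------
  if ("discover" %in% stages && (force || !file.exists(loci_path))) {
    need(file.path(panel_dir, "truth.json"), "synth")
    dir.create(disc_dir, showWarnings = FALSE)
    refs <- read_mature_mirnas(file.path(panel_dir, "mature_refs.fa"))
    loci_all <- list()
    for (lin in config$lineage_names) {
      genome <- read_genome(file.path(panel_dir, "genomes",
                                      paste0(safe_name(lin), ".fa")))
      loci <- discover_mirnome(genome, refs, lineage = lin,
                               max_mismatch = config$max_mismatch,
                               flank_up = config$flank,
                               flank_down = config$flank, engine = engine)
      write_loci_gff3(loci, file.path(disc_dir,
                                      paste0(safe_name(lin), ".gff3")))
      loci_all[[lin]] <- loci
    }
    loci_tab <- do.call(rbind, loci_all)
    rownames(loci_tab) <- NULL
    write_family_precursors(loci_tab, file.path(disc_dir, "precursors"))
    loci_tab$precursor_seq <- NULL
    write_tsv(loci_tab, loci_path)
    state$loci <- loci_tab
  }

  # ---- pangenome --------------------------------------------------------
  if ("pangenome" %in% stages &&
      (force || !file.exists(file.path(pan_dir, "presence.tsv")))) {
    loci <- get_loci()
    dir.create(pan_dir, showWarnings = FALSE)
    sets <- lapply(stats::setNames(config$lineage_names,
                                   config$lineage_names),
                   function(l) unique(loci$family[loci$lineage == l]))
    pm <- build_presence_matrix(sets)
    write_presence_tsv(pm, file.path(pan_dir, "presence.tsv"))
    C <- pairwise_conservation(pm)
    write_tsv(cbind(data.frame(lineage = rownames(C)),
                    as.data.frame(round(C, 3), row.names = NULL)),
              file.path(pan_dir, "conservation_matrix.tsv"))
    state$pm <- pm
  }

  # ---- repeats ----------------------------------------------------------
  if ("repeats" %in% stages && (force || !file.exists(rep_path))) {
    loci <- get_loci()
    need(file.path(panel_dir, "truth.json"), "synth")
    dir.create(rep_dir, showWarnings = FALSE)
    loci_rep <- list()
    for (lin in config$lineage_names) {
      reps <- read_repeat_bed(file.path(panel_dir, "repeats",
                                        paste0(safe_name(lin), ".bed")))
      sub <- loci[loci$lineage == lin, , drop = FALSE]
      loci_rep[[lin]] <- annotate_repetitive(sub, reps)
    }
    loci <- do.call(rbind, loci_rep)
    rownames(loci) <- NULL
    write_tsv(loci, rep_path)
    fs <- family_summary(get_pm(), loci)
    write_tsv(fs, file.path(rep_dir, "family_summary.tsv"))
    state$loci_rep <- loci
    state$family_summary <- fs
  }

  # ---- targets ----------------------------------------------------------
  if ("targets" %in% stages && (force || !file.exists(hits_path))) {
    loci <- get_loci()
    dir.create(tgt_dir, showWarnings = FALSE)
    refs <- read_mature_mirnas(need(file.path(panel_dir, "mature_refs.fa"),
                                    "synth"))
    matures <- stats::setNames(refs$sequence, refs$family)
    mirnomes <- lapply(stats::setNames(config$lineage_names,
                                       config$lineage_names),
                       function(l) unique(loci$family[loci$lineage == l]))
    hits <- predict_targets(matures, get_cds(), mirnomes = mirnomes,
                            expectation_max = expectation_max,
                            upe_max = upe_max, use_upe = TRUE,
                            engine = engine)
    write_tsv(hits, hits_path)
    state$hits <- hits
  }

  # ---- networks ---------------------------------------------------------
  if ("networks" %in% stages &&
      (force || !file.exists(file.path(net_dir, "teams.tsv")))) {
    hits <- get_hits()
    dir.create(net_dir, showWarnings = FALSE)
    mult <- multiplicity_distribution(hits)
    write_tsv(cbind(data.frame(bin = colnames(mult$mirna_side)),
                    mirna_mean = mult$mirna_mean,
                    target_mean = mult$target_mean),
              file.path(net_dir, "multiplicity.tsv"))
    teams <- find_teams(hits, min_support = 1L)
    write_tsv(teams, file.path(net_dir, "teams.tsv"))
    # pool targeted transcripts per conservation group, cluster at the
    # identity threshold, export cluster representatives
    pm <- get_pm()
    all_cds <- unlist(unname(get_cds()))
    grp <- classify_conservation(pm$counts,
                                 n_lineages = length(pm$lineages))
    clusters_by_group <- list()
    for (g in levels(grp)) {
      fams_g <- pm$families[grp == g]
      txs <- unique(hits$transcript[hits$family %in% fams_g])
      if (length(txs) == 0) next
      cl <- cluster_transcripts(all_cds[txs], identity = identity)
      clusters_by_group[[g]] <- cl
      reps <- cluster_representatives(cl, all_cds[txs])
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(reps),
        file.path(net_dir, paste0("representatives_", g, ".fa")))
    }
    state$mult <- mult
    state$teams <- teams
    state$clusters <- clusters_by_group
    state$ran_networks <- TRUE
  }

  # ---- summary ----------------------------------------------------------
  summary_path <- file.path(out_dir, "summary.json")
  ran_any <- !is.null(state$panel) || !is.null(state$loci) ||
    !is.null(state$hits) || isTRUE(state$ran_networks)
  if (force || ran_any || !file.exists(summary_path)) {
    summ <- list(engine = engine, stages = stages, seed = config$seed)
    pm <- tryCatch(get_pm(), error = function(e) NULL)
    if (!is.null(pm)) {
      grp <- classify_conservation(pm$counts,
                                   n_lineages = length(pm$lineages))
      summ$families_per_lineage <- as.list(colSums(pm$present))
      summ$group_sizes <- as.list(table(grp))
      summ$n_families <- length(pm$families)
    }
    if (!is.null(state$family_summary)) {
      fs <- state$family_summary
      summ$repetitive_families <-
        fs$family[!is.na(fs$n_repetitive) &
                  fs$n_repetitive == fs$n_precursors & fs$n_precursors > 0]
    }
    if (!is.null(state$teams)) summ$teams <- state$teams
    jsonlite::write_json(summ, summary_path, auto_unbox = TRUE,
                         dataframe = "columns", digits = NA)
  } else {
    summ <- jsonlite::read_json(summary_path, simplifyVector = TRUE)
  }
  invisible(summ)
}
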