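## End-to-end orchestration: consensus -> subtraction -> scan -> classify
## -> profile, over an on-disk cohort (the layout written by
## [write_cohort()]). Stage-by-stage counts are logged to stderr as JSON
## lines; outputs are plain TSV/JSON plus a Markdown summary, and re-runs
## with identical inputs are byte-identical (no randomness in analysis).

#' Read a cohort design TSV
#' @param path TSV with sample_id, group, guide_id, replicate_of,
#'   parent_id.
#' @return a `cohort_design`.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  cohort_design(df)
}

#' Read a guide table TSV
#' @param path TSV with guide_id, protospacer, nuclease, pam_patterns
#'   (";"-separated), and optional target_chrom/target_start/target_strand.
#' @return named list of `guide_spec`.
#' @export
read_guides_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  guides <- lapply(seq_len(nrow(df)), function(i) {
    target <- NULL
    if (!is.null(df$target_chrom) && !is.na(df$target_chrom[i]))
      target <- list(chrom = df$target_chrom[i],
                     start = as.integer(df$target_start[i]),
                     strand = df$target_strand[i])
    guide_spec(df$guide_id[i], df$protospacer[i], df$nuclease[i],
               strsplit(df$pam_patterns[i], ";", fixed = TRUE)[[1]],
               target = target)
  })
  names(guides) <- df$guide_id
  guides
}

#' Pipeline configuration
#'
#' @param input_dir cohort directory (genome.fa, design.tsv, guides.tsv,
#'   vcf/<sample>__<caller>.vcf).
#' @param output_dir report directory (created by [run_pipeline()]).
#' @param min_af consensus allele-frequency floor (default 0.10).
#' @param max_mismatch protospacer mismatch budget for site scanning
#'   (default 3).
#' @param seed_len seed length for seed-mismatch reporting (default 18).
#' @param window site-assignment window in bp (default 5).
#' @param homology_budget poor-homology threshold (default 6).
#' @param include_nag add the alternative NAG PAM when scanning Cas9
#'   guides for classification (default TRUE).
#' @param features optional GFF3/BED feature file for enrichment.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            min_af = 0.10, max_mismatch = 3,
                            seed_len = 18, window = 5,
                            homology_budget = 6, include_nag = TRUE,
                            features = NULL) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 min_af = min_af, max_mismatch = max_mismatch,
                 seed_len = seed_len, window = window,
                 homology_budget = homology_budget,
                 include_nag = include_nag, features = features),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#' @param path config file; keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Validate a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @return character vector of problems (empty iff [run_pipeline()]'s
#'   preconditions hold).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  if (is.null(config$input_dir) || !dir.exists(config$input_dir))
    add("input_dir does not exist")
  else {
    for (f in c("genome.fa", "design.tsv", "guides.tsv"))
      if (!file.exists(file.path(config$input_dir, f)))
        add(paste0("missing input file: ", f))
    if (!dir.exists(file.path(config$input_dir, "vcf")))
      add("missing input directory: vcf/")
  }
  if (is.null(config$output_dir) || !nzchar(config$output_dir))
    add("output_dir is not set")
  if (config$min_af < 0 || config$min_af > 1)
    add("min_af out of range [0,1]")
  if (config$max_mismatch < 0) add("max_mismatch must be >= 0")
  if (config$seed_len < 1) add("seed_len must be >= 1")
  if (config$window < 0) add("window must be >= 0")
  if (!is.null(config$features) && !file.exists(config$features))
    add("features file does not exist")
  problems
}

log_stage <- function(stage, ...) {
  message(jsonlite::toJSON(c(list(stage = stage), list(...)),
                           auto_unbox = TRUE))
}

#' Run the whole adjudication pipeline
#'
#' Stages: per-sample multi-caller consensus with AF floor; subtraction of
#' control-cohort variants (WT groups first, then tissue-culture and
#' transformation controls); guide site scanning; per-sample off-target
#' classification using replicate lines and the pedigree; per-sample
#' profiling (counts, SNV spectrum, AF bins, optional feature enrichment).
#' Writes `classification.tsv`, `guide_summary.json`, `ledger.tsv`,
#' `profile.tsv`, `sites.bed` and `summary.md` into the output directory.
#'
#' @param config a `pipeline_config` (or path to a YAML/JSON config).
#' @return invisibly, a list with status (0 on success), output paths,
#'   and the in-memory tables (classified, guide_summary, profile).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  problems <- validate_config(config)
  if (length(problems) > 0)
    stop_input("invalid configuration:\n  - ",
               paste(problems, collapse = "\n  - "))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- read_genome_fasta(file.path(config$input_dir, "genome.fa"))
  design <- read_design_tsv(file.path(config$input_dir, "design.tsv"))
  guides <- read_guides_tsv(file.path(config$input_dir, "guides.tsv"))
  log_stage("load", n_samples = nrow(design), n_guides = length(guides),
            genome_bp = genome_length(genome))

  ## ---- consensus ----
  vcf_dir <- file.path(config$input_dir, "vcf")
  consensus <- list()
  for (sid in design$sample_id) {
    files <- list.files(vcf_dir, pattern = paste0("^", sid, "__.*\\.vcf$"),
                        full.names = TRUE)
    if (length(files) < 2)
      stop_input("stage consensus: sample ", sid,
                 " has fewer than 2 caller VCFs")
    sets <- lapply(files, function(f) {
      cid <- sub("\\.vcf$", "", sub("^.*__", "", basename(f)))
      read_vcf(f, sample_id = sid, caller_id = cid)
    })
    n_in <- sum(vapply(sets, nrow, integer(1)))
    consensus[[sid]] <- consensus_sample(sets, genome,
                                         min_af = config$min_af)
    log_stage("consensus", sample = sid, calls_in = n_in,
              consensus_out = nrow(consensus[[sid]]))
  }

  ## ---- control subtraction ----
  control_groups <- c("WT_G1", "WT_G2", "WT_G3", "TC_only", "Agro",
                      "Cas9_backbone", "Cpf1_backbone")
  controls <- list()
  for (grp in control_groups) {          # WT groups first
    for (sid in design$sample_id[design$group == grp])
      controls[[paste0(grp, ":", sid)]] <- consensus[[sid]]
  }
  names(controls) <- sub(":.*$", "", names(controls))
  edited_ids <- design$sample_id[grepl("^Edited_", design$group)]
  post <- list(); ledgers <- list()
  for (sid in edited_ids) {
    sub <- subtract_controls(consensus[[sid]], controls)
    post[[sid]] <- sub$variants
    ledgers[[sid]] <- sub$ledger
    log_stage("subtract", sample = sid, in_ = nrow(consensus[[sid]]),
              retained = nrow(sub$variants), absorbed = nrow(sub$ledger))
  }

  ## ---- scan ----
  sites_by_guide <- list()
  for (gid in names(guides)) {
    g <- guides[[gid]]
    pams <- g$pam_patterns
    if (config$include_nag && g$nuclease == "Cas9" && !"NAG" %in% pams)
      pams <- c(pams, "NAG")
    sites_by_guide[[gid]] <- find_sites(genome, g, config$max_mismatch,
                                        pam_patterns = pams,
                                        seed_len = config$seed_len)
    log_stage("scan", guide = gid, n_sites = nrow(sites_by_guide[[gid]]))
  }

  ## ---- classify ----
  pedigree_of <- function(sid) {
    keys <- character(0)
    p <- design$parent_id[design$sample_id == sid]
    while (!is.na(p) && p %in% names(consensus)) {
      keys <- c(keys, variant_key(consensus[[p]]))
      p <- design$parent_id[design$sample_id == p]
    }
    keys
  }
  classified <- list()
  for (sid in edited_ids) {
    row <- design[design$sample_id == sid, ]
    gid <- row$guide_id
    sites <- sites_by_guide[[gid]]
    g <- guides[[gid]]
    target_idx <- NA_integer_
    if (!is.null(g$target)) {
      m <- which(sites$chrom == g$target$chrom &
                   sites$start == g$target$start &
                   sites$strand == g$target$strand)
      if (length(m) > 0) target_idx <- m[1]
    } else if (nrow(sites) > 0) {
      target_idx <- order(sites$n_mismatch, sites$seed_mismatch)[1]
    }
    ## independent replicate line: same guide, same group, different id
    rep_id <- setdiff(design$sample_id[design$group == row$group &
                                         !is.na(design$guide_id) &
                                         design$guide_id == gid], sid)
    rep_set <- if (length(rep_id) > 0) post[[rep_id[1]]] else NULL
    cls <- classify_variants(
      post[[sid]], sites, target_site_idx = target_idx,
      replicate_variants = rep_set, controls_ledger = ledgers[[sid]],
      pedigree_keys = pedigree_of(sid), window = config$window,
      homology_budget = config$homology_budget)
    led <- ledgers[[sid]]
    if (nrow(led) > 0) {
      led_cls <- classify_variants(led, sites,
                                   target_site_idx = target_idx,
                                   controls_ledger = led,
                                   window = config$window,
                                   homology_budget = config$homology_budget)
      led_cls$absorbed_by_group <- NULL
      cls <- rbind(cls, led_cls)
    }
    cls$guide_id <- gid
    classified[[sid]] <- cls
    log_stage("classify", sample = sid, n = nrow(cls))
  }
  all_cls <- do.call(rbind, classified) %||% data.frame()
  guide_summary <- summarize_guides(all_cls)

  ## ---- profile ----
  track <- if (!is.null(config$features))
    read_feature_track(config$features, genome) else NULL
  prof <- lapply(design$sample_id, function(sid) {
    v <- consensus[[sid]]
    snv <- v[v$kind == "SNV", , drop = FALSE]
    spec <- snv_spectrum(snv)
    bins <- af_bins(v)
    data.frame(sample_id = sid, group = design$group[design$sample_id == sid],
               n_variants = nrow(v), n_snv = nrow(snv),
               n_indel = sum(v$kind %in% c("INS", "DEL")),
               ts_tv = spec$ts_tv,
               gc_to_at = spec$gc_to_at_fraction,
               somatic_like = bins[["somatic_like"]],
               heterozygous_like = bins[["heterozygous_like"]],
               homozygous_like = bins[["homozygous_like"]],
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, prof)
  log_stage("profile", n_samples = nrow(prof))

  ## ---- write outputs ----
  out <- function(f) file.path(config$output_dir, f)
  write_classification_tsv(all_cls, out("classification.tsv"))
  jsonlite::write_json(guide_summary, out("guide_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_ledger_tsv(do.call(rbind, ledgers) %||% data.frame(),
                   out("ledger.tsv"))
  utils::write.table(prof, out("profile.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  all_sites <- do.call(rbind, sites_by_guide)
  write_sites_bed(all_sites, out("sites.bed"))
  if (!is.null(track)) {
    enr <- feature_enrichment(do.call(rbind, consensus), track)
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  md <- c(
    "# Off-target adjudication report", "",
    sprintf("- samples: %d (%d edited)", nrow(design), length(edited_ids)),
    sprintf("- guides: %d, flagged unsafe: %d", nrow(guide_summary),
            sum(!guide_summary$safe)),
    sprintf("- validated off-target loci: %d",
            sum(guide_summary$n_validated_loci)), "",
    "## Per-guide summary", "",
    paste0("| guide | validated loci | candidate loci | safe |"),
    paste0("|---|---|---|---|"),
    sprintf("| %s | %d | %d | %s |", guide_summary$guide_id,
            guide_summary$n_validated_loci, guide_summary$n_candidate_loci,
            ifelse(guide_summary$safe, "yes", "NO")))
  writeLines(md, out("summary.md"))
  log_stage("done", output_dir = config$output_dir)
  invisible(list(status = 0L,
                 outputs = vapply(c("classification.tsv",
                                    "guide_summary.json", "ledger.tsv",
                                    "profile.tsv", "sites.bed",
                                    "summary.md"), out, character(1)),
                 consensus = consensus, classified = all_cls,
                 guide_summary = guide_summary, profile = prof))
}
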