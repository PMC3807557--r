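## End-to-end orchestration: catalog -> LD -> intersect -> sites/diffs
## -> prioritize -> hub, with stage TSVs, funnel counts and a run
## manifest.

#' Default pipeline configuration
#'
#' Input paths plus the analysis parameters, whose defaults equal the
#' published procedure: association p < 1e-5, LD at r-squared > 0.6
#' within +/- 1 Mb, very strong LD at r-squared > 0.9, hub weighting 1.5
#' for 8mers and sites within 60 nt, conservation 5, 100,000 Monte Carlo
#' replicates.
#'
#' @param catalog,panels,mirna_gff,mirna_fasta,promoter_bed,utr_table,utr_mappings
#'   required input paths; `panels` is a named list, super-population ->
#'   phased VCF.
#' @param exon_bed,symbol_map,nonsyn_vcf,transcriptional,eqtl,tarbase,trait_genes
#'   optional annotation inputs (the hub stage runs only when
#'   `trait_genes` is given).
#' @param p_threshold,r2_threshold,strong_ld,window_bp,weight,spacing,reps,min_conservation,hub_alpha,score_mode,seed
#'   analysis parameters.
#' @return a named list (class `mirtas_config`).
#' @export
pipeline_config <- function(catalog, panels, mirna_gff, mirna_fasta,
                            promoter_bed, utr_table, utr_mappings,
                            exon_bed = NULL, symbol_map = NULL,
                            nonsyn_vcf = NULL, transcriptional = NULL,
                            eqtl = NULL, tarbase = NULL,
                            trait_genes = NULL,
                            p_threshold = 1e-5, r2_threshold = 0.6,
                            strong_ld = 0.9, window_bp = 1e6,
                            weight = 1.5, spacing = 60L, reps = 100000L,
                            min_conservation = 5L, hub_alpha = 0.01,
                            score_mode = "site", seed = NULL) {
  cfg <- list(catalog = catalog, panels = panels, mirna_gff = mirna_gff,
              mirna_fasta = mirna_fasta, promoter_bed = promoter_bed,
              utr_table = utr_table, utr_mappings = utr_mappings,
              exon_bed = exon_bed, symbol_map = symbol_map,
              nonsyn_vcf = nonsyn_vcf, transcriptional = transcriptional,
              eqtl = eqtl, tarbase = tarbase, trait_genes = trait_genes,
              p_threshold = p_threshold, r2_threshold = r2_threshold,
              strong_ld = strong_ld, window_bp = window_bp,
              weight = weight, spacing = as.integer(spacing),
              reps = as.integer(reps),
              min_conservation = as.integer(min_conservation),
              hub_alpha = hub_alpha, score_mode = score_mode, seed = seed)
  class(cfg) <- "mirtas_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' Accepts JSON (object syntax) or a flat `key = value` file; keys match
#' the arguments of [pipeline_config()], with `panels` given as
#' `panel.EUR = path` style keys in the flat dialect.
#'
#' @param path config file path.
#' @return a `mirtas_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: %s", path)
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = " "))
  if (startsWith(first, "{")) {
    vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                               simplifyVector = TRUE)
  } else {
    txt <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
    kv <- regmatches(txt, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", txt))
    bad <- lengths(kv) != 3L
    if (any(bad)) config_error("unparsable config line: %s", txt[bad][1L])
    vals <- stats::setNames(lapply(kv, `[[`, 3L),
                            vapply(kv, `[[`, character(1), 2L))
    pan <- grepl("^panel\\.", names(vals))
    panels <- vals[pan]
    names(panels) <- sub("^panel\\.", "", names(panels))
    vals <- vals[!pan]
    if (length(panels)) vals$panels <- panels
    num <- c("p_threshold", "r2_threshold", "strong_ld", "window_bp",
             "weight", "spacing", "reps", "min_conservation", "hub_alpha",
             "seed")
    for (k in intersect(num, names(vals))) {
      vals[[k]] <- as.numeric(vals[[k]])
    }
  }
  if (is.data.frame(vals$panels)) vals$panels <- as.list(vals$panels)
  do.call(pipeline_config, vals)
}

.check_inputs <- function(config) {
  required <- c("catalog", "mirna_gff", "mirna_fasta", "promoter_bed",
                "utr_table", "utr_mappings")
  for (k in required) {
    if (is.null(config[[k]])) config_error("config is missing '%s'", k)
    if (!file.exists(config[[k]])) {
      config_error("input for '%s' does not exist: %s", k, config[[k]])
    }
  }
  if (is.null(config$panels) || !length(config$panels)) {
    config_error("config is missing 'panels'")
  }
  for (p in names(config$panels)) {
    if (!file.exists(config$panels[[p]])) {
      config_error("panel VCF for %s does not exist: %s", p,
                   config$panels[[p]])
    }
  }
  optional <- c("exon_bed", "symbol_map", "nonsyn_vcf", "transcriptional",
                "eqtl", "tarbase", "trait_genes")
  for (k in optional) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      config_error("input for '%s' does not exist: %s", k, config[[k]])
    }
  }
  invisible(TRUE)
}

## reference sites (with conservation) over every admitted human UTR
.reference_site_index <- function(admitted, utr_all, mirnas) {
  out <- vector("list", nrow(admitted))
  for (i in seq_len(nrow(admitted))) {
    id <- admitted$id[i]
    s <- find_sites(admitted$sequence[i], mirnas, admitted$gene_symbol[i])
    orth <- utr_all[utr_all$id == id & utr_all$species != "human", ,
                    drop = FALSE]
    s <- annotate_conservation(
      s, stats::setNames(as.list(orth$sequence), orth$species), mirnas)
    out[[i]] <- s
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- find_sites("AAAA", mirnas[0, , drop = FALSE])
    res$conservation <- integer(0)
  }
  res$allele_context <- rep("reference", nrow(res))
  rownames(res) <- NULL
  res
}

#' Run the full TAS cataloging and prioritization pipeline
#'
#' Executes the stages in order (catalog -> LD expansion -> regulome
#' intersection -> site prediction and allelic diffs -> prioritization
#' -> hub scan), writing one TSV per stage plus funnel counts and a
#' machine-readable run manifest into `out_dir`. An empty catalog yields
#' empty downstream tables and a warning, not an error. Reruns with the
#' same config and seed produce identical outputs.
#'
#' @param config a `mirtas_config` (see [pipeline_config()]) or a path
#'   to a config file.
#' @param out_dir output directory (created if needed).
#' @return object of class `mirtas_run`: stage tables, funnel counts and
#'   output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .check_inputs(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  ## --- stage 1: catalog
  assoc <- parse_catalog(config$catalog, config$p_threshold)
  assoc$population <- assign_superpopulation(assoc$ancestry_text)
  write_tsv(assoc, pth("01_catalog.tsv"))
  if (nrow(assoc) == 0L) {
    warning("no associations pass the catalog filters; downstream tables are empty")
  }

  ## --- stage 2: LD blocks
  panels <- lapply(config$panels, read_haplotype_vcf)
  for (p in names(panels)) panels[[p]]$population <- p
  blocks <- list(); unresolved <- character(0)
  seen <- character(0)
  for (i in seq_len(nrow(assoc))) {
    pop <- assoc$population[i]
    key <- paste(assoc$index_snp[i], pop)
    if (key %in% seen) next
    seen <- c(seen, key)
    if (!pop %in% names(panels)) {
      warning("no haplotype panel configured for ", pop,
              "; association for ", assoc$index_snp[i], " skipped")
      unresolved <- c(unresolved, assoc$index_snp[i])
      next
    }
    b <- withCallingHandlers(
      expand_ld_block(assoc$index_snp[i], panels[[pop]],
                      r2_threshold = config$r2_threshold,
                      window_bp = config$window_bp,
                      trait = assoc$trait[i]),
      warning = function(w) {
        log_msg("%s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (b$unresolved) unresolved <- c(unresolved, assoc$index_snp[i])
    else blocks[[length(blocks) + 1L]] <- b
  }
  block_tab <- ld_blocks_table(blocks)
  write_tsv(block_tab, pth("02_ld_blocks.tsv"))

  ## --- stage 3: regulome elements and intersection
  pre <- read_mirna_gff(config$mirna_gff)
  prom <- read_bed_elements(config$promoter_bed, "promoter")
  utr_all <- read_utr_table(config$utr_table, config$symbol_map)
  human <- utr_all[utr_all$species == "human", , drop = FALSE]
  mappings <- read_utr_mappings(config$utr_mappings)
  fl <- filter_utr_mappings(human, mappings)
  write_tsv(fl$rejected[, c("id", "gene_symbol", "reason")],
            pth("03_utr_rejects.tsv"))
  elements <- suppressWarnings(c(pre, prom, utr_elements(fl$admitted)))
  tas_el <- intersect_tas(block_tab, elements)
  write_tsv(tas_el, pth("03_tas_elements.tsv"))

  ## --- stage 4: reference sites, conservation, allelic diffs
  mirnas <- read_mirna_fasta(config$mirna_fasta)
  site_index <- .reference_site_index(fl$admitted, utr_all, mirnas)
  write_tsv(site_index, pth("04_sites_ref.tsv"))

  tas_snps <- unique(block_tab[, c("member_snp", "chrom", "pos",
                                   "population")])
  diffs <- list()
  predicted_pairs <- list()  # per index_snp: (mirna, gene) with a TAS in the site span
  utr3_rows <- tas_el[tas_el$kind == "utr3", , drop = FALSE]
  for (gene in unique(utr3_rows$owner)) {
    gi <- which(fl$admitted$gene_symbol == gene)[1L]
    mapping <- fl$admitted[gi, c("chrom", "start", "end", "strand")]
    rows <- utr3_rows[utr3_rows$owner == gene, , drop = FALSE]
    for (pop in unique(rows$population)) {
      panel <- panels[[pop]]
      ids <- unique(rows$snp[rows$population == pop])
      meta <- panel$snps[panel$snps$id %in% ids, , drop = FALSE]
      usnps <- map_snps_to_utr(meta, mapping)
      if (nrow(usnps) == 0L) next
      d <- utr_site_diffs(fl$admitted$sequence[gi], usnps, mirnas, gene)
      if (nrow(d)) {
        d$population <- pop
        diffs[[length(diffs) + 1L]] <- d
      }
      ## site-span overlap for validated-pair support
      ref_sites <- site_index[site_index$gene_symbol == gene, ,
                              drop = FALSE]
      for (k in seq_len(nrow(usnps))) {
        inside <- ref_sites[usnps$utr_pos[k] >= ref_sites$utr_offset + 1L &
                              usnps$utr_pos[k] <= ref_sites$utr_offset +
                              ref_sites$site_length, , drop = FALSE]
        if (nrow(inside) == 0L) next
        idxs <- unique(rows$index_snp[rows$snp == usnps$id[k]])
        for (ix in idxs) {
          predicted_pairs[[ix]] <- rbind(
            predicted_pairs[[ix]],
            data.frame(mirna = inside$mirna, gene = gene,
                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  diff_tab <- do.call(rbind, diffs)
  if (is.null(diff_tab)) {
    diff_tab <- utr_site_diffs("AAAAAAAAAAAA",
                               data.frame(id = character(0),
                                          utr_pos = integer(0),
                                          ref = character(0),
                                          alt = character(0)),
                               mirnas[0, , drop = FALSE])
    diff_tab$population <- character(0)
  }
  write_tsv(diff_tab, pth("04_site_diffs.tsv"))

  ## --- stage 5: prioritization
  exons <- if (!is.null(config$exon_bed)) {
    read_bed_elements(config$exon_bed, "exon")
  } else NULL
  nonsyn_ids <- if (!is.null(config$nonsyn_vcf)) {
    read_nonsyn_vcf(config$nonsyn_vcf)
  } else character(0)
  trans_ids <- if (!is.null(config$transcriptional)) {
    read_snp_set(config$transcriptional)
  } else character(0)
  eqtl_ids <- if (!is.null(config$eqtl)) read_snp_set(config$eqtl)
    else character(0)
  tarbase <- if (!is.null(config$tarbase)) read_tarbase(config$tarbase)
    else NULL
  annotations <- lapply(blocks, function(b) {
    annotate_block(b, exons, nonsyn_ids, trans_ids, eqtl_ids, tarbase,
                   predicted_pairs[[b$index_snp]],
                   strong_ld = config$strong_ld)
  })
  names(annotations) <- vapply(blocks, `[[`, character(1), "index_snp")
  prioritized <- prioritize_table(tas_el, annotations)
  write_tsv(prioritized, pth("05_prioritized.tsv"))

  ## --- stage 6: hub scan
  hub <- NULL
  if (!is.null(config$trait_genes) && nrow(fl$admitted) > 0L) {
    tg <- read_tsv(config$trait_genes)
    if (!all(c("trait", "gene") %in% names(tg))) {
      config_error("trait gene lists must have columns: trait, gene")
    }
    universe <- unique(fl$admitted$gene_symbol)
    utr_lengths <- stats::setNames(nchar(fl$admitted$sequence),
                                   fl$admitted$gene_symbol)
    cfg <- hub_config(weight = config$weight, spacing_nt = config$spacing,
                      reps = config$reps,
                      min_conservation = config$min_conservation,
                      rng_seed = config$seed,
                      score_mode = config$score_mode)
    hub <- hub_scan(tg, mirnas = mirnas$name, gene_universe = universe,
                    site_index = site_index, utr_lengths = utr_lengths,
                    config = cfg, alpha = config$hub_alpha)
    write_tsv(as.data.frame(hub), pth("06_hub.tsv"))
  }

  ## --- funnel + manifest
  funnel <- pipeline_funnel(assoc, blocks, unresolved, tas_el, diff_tab,
                            prioritized, hub)
  write_tsv(funnel, pth("funnel.tsv"))
  inputs <- Filter(Negate(is.null),
                   c(config[c("catalog", "mirna_gff", "mirna_fasta",
                              "promoter_bed", "utr_table", "utr_mappings",
                              "exon_bed", "symbol_map", "nonsyn_vcf",
                              "transcriptional", "eqtl", "tarbase",
                              "trait_genes")],
                     config$panels))
  manifest <- list(
    tool = "mirtas",
    version = as.character(utils::packageVersion("mirtas")),
    rng_seed = config$seed,
    parameters = config[c("p_threshold", "r2_threshold", "strong_ld",
                          "window_bp", "weight", "spacing", "reps",
                          "min_conservation", "hub_alpha", "score_mode")],
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    counts = stats::setNames(as.list(funnel$count), funnel$stage)
  )
  jsonlite::write_json(manifest, pth("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(
    config = config, out_dir = out_dir, associations = assoc,
    blocks = blocks, unresolved = unresolved, tas_elements = tas_el,
    site_index = site_index, site_diffs = diff_tab,
    prioritized = prioritized, hub = hub, funnel = funnel,
    manifest = manifest
  ), class = "mirtas_run")
}

## unique created/abolished site events (collapsing per-haplotype
## duplicates of the same site change)
.diff_events <- function(diff_tab) {
  unique(diff_tab[, c("gene_symbol", "mirna", "utr_offset", "site_type",
                      "direction")])
}

#' Funnel counts of a pipeline run
#'
#' Per-stage record counts mirroring the analysis funnel: associations
#' kept, LD blocks, unique TASs, unique TASs per element kind, unique
#' created/abolished site events, tier counts, and significant hub
#' pairs.
#'
#' @param assoc,blocks,unresolved,tas_el,diff_tab,prioritized,hub stage
#'   results (see [run_pipeline()]).
#' @return data.frame with `stage` and `count`.
#' @export
pipeline_funnel <- function(assoc, blocks, unresolved, tas_el, diff_tab,
                            prioritized, hub = NULL) {
  ev <- .diff_events(diff_tab)
  uniq_per_kind <- function(kind) {
    length(unique(tas_el$snp[tas_el$kind == kind]))
  }
  tiers <- table(factor(prioritized$tier,
                        levels = c("top", "supported", "other")))
  rows <- data.frame(
    stage = c("associations_kept", "blocks_resolved", "blocks_unresolved",
              "unique_tas", "tas_pre_mirna", "tas_promoter", "tas_utr3",
              "sites_created", "sites_abolished",
              "tier_top", "tier_supported", "tier_other",
              "hub_significant"),
    count = c(nrow(assoc), length(blocks), length(unresolved),
              length(unique(unlist(lapply(blocks, function(b)
                b$members$snp)))),
              uniq_per_kind("pre_mirna"), uniq_per_kind("promoter"),
              uniq_per_kind("utr3"),
              sum(ev$direction == "created"),
              sum(ev$direction == "abolished"),
              as.integer(tiers[["top"]]), as.integer(tiers[["supported"]]),
              as.integer(tiers[["other"]]),
              if (is.null(hub)) 0L else sum(hub$significant)),
    stringsAsFactors = FALSE
  )
  rows
}

#' @export
print.mirtas_run <- function(x, ...) {
  cat("miRNA-regulome TAS pipeline run:", x$out_dir, "\n")
  print.data.frame(x$funnel)
  invisible(x)
}

#' Summarize a pipeline run as a funnel report
#'
#' @param run a `mirtas_run` (or the output directory of one).
#' @return the funnel data.frame, invisibly; prints a plain-text report.
#' @export
summarize_run <- function(run) {
  funnel <- if (inherits(run, "mirtas_run")) {
    run$funnel
  } else {
    f <- file.path(run, "funnel.tsv")
    if (!file.exists(f)) config_error("no funnel.tsv under %s", run)
    read_tsv(f)
  }
  cat("== TAS funnel ==\n")
  for (i in seq_len(nrow(funnel))) {
    cat(sprintf("  %-18s %d\n", funnel$stage[i], funnel$count[i]))
  }
  if (inherits(run, "mirtas_run") && !is.null(run$hub)) {
    cat("== top hub hits ==\n")
    top <- utils::head(as.data.frame(run$hub), 3L)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s x %s: p = %.4g%s\n", top$mirna[i], top$trait[i],
                  top$empirical_p[i],
                  if (top$significant[i]) " *" else ""))
    }
  }
  invisible(funnel)
}
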