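#' Default pipeline configuration
#'
#' One nested list holds every stage's parameters; [run_pipeline()] merges
#' a user configuration (list or YAML file) over these defaults and
#' validates it before any computation. Defaults mirror the experimental
#' design being emulated: four strains in all ordered pairings, LC-MS
#' sampling on days 2-6 in triplicate with pooled QCs every 6th
#' injection, RNA-seq on days 2-4, colony imaging on day 6 with n = 4.
#'
#' @return nested list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    strains = c("A", "B", "C", "D"),
    days = 2:6,
    replicates = 3L,
    stages = c("simulate", "rnaseq", "metabolomics", "colonies",
               "enrichment", "report"),
    simulate = list(genome_len = 20000L, n_genes = 12L, gene_len = 500L,
                    shared_fraction = 0, rrna_len = 1200L),
    rnaseq = list(days = 2:4, depth = 30, read_len = 60L, k = 21L,
                  rrna_fraction = 0.05, multiplex_pairs = TRUE,
                  test_day = 4L, mode = "wald", min_kmer_fraction = 0.5,
                  min_match_frac = 0.5),
    metabolomics = list(n_features = 200L, n_noise_features = 20L,
                        noise_sd = 0.2, drift_slope = 0.3,
                        missing_rate = 0.05, qc_every = 6L,
                        alpha = 0.05, lfc_min = 1.5, knn_k = 5L,
                        lambda = "auto", min_present_frac = 2 / 3,
                        blank_ratio = 3, rt_window = 5, min_corr = 0.9,
                        adduct_pairs = 5L),
    colonies = list(image_px = 260L, plate_mm = 90, n_images = 4L,
                    day = 6L, base_radius_px = 26, min_area_px = 50),
    enrichment = list(min_size = 10L, p_cut = 0.05, n_pathways = 12L,
                      genes_per_pathway = 12L)
  )
}

validate_config <- function(config) {
  chk <- function(cond, msg) if (!cond) stopf("invalid config: %s", msg)
  chk(is.numeric(config$seed) && config$seed == round(config$seed),
      "seed must be an integer")
  chk(length(config$strains) >= 2 && !anyDuplicated(config$strains),
      "need >= 2 unique strains")
  chk(config$replicates >= 2, "replicates must be >= 2")
  m <- config$metabolomics
  chk(m$alpha > 0 && m$alpha <= 1, "metabolomics$alpha must be in (0, 1]")
  chk(m$lfc_min >= 0, "metabolomics$lfc_min must be >= 0")
  chk(m$qc_every >= 2, "metabolomics$qc_every must be >= 2")
  chk(m$missing_rate >= 0 && m$missing_rate < 1,
      "metabolomics$missing_rate must be in [0, 1)")
  chk(m$knn_k >= 1, "metabolomics$knn_k must be >= 1")
  chk(config$enrichment$min_size >= 1, "enrichment$min_size must be >= 1")
  chk(config$rnaseq$k >= 11, "rnaseq$k must be >= 11")
  chk(config$simulate$shared_fraction >= 0 &&
        config$simulate$shared_fraction < 1,
      "simulate$shared_fraction must be in [0, 1)")
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with any subset of [default_config()]'s fields.
#' @return full validated config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

# The planted world the default pipeline simulates: a constitutive,
# diffusible DFO-B-like ion produced by strain C (at the [M+2H]2+ mass),
# induced features produced by A in response to C and to B, and DE genes
# in A next to C.
default_truth <- function(config) {
  st <- config$strains
  pf <- de <- NULL
  if (all(c("A", "C") %in% st)) {
    pf <- data.frame(
      feature_id = c("F0001", "F0002", "F0003"),
      producer = c("C", "A", "A"),
      responder = c(NA, "C", if ("B" %in% st) "B" else "C"),
      lfc = c(4, 3, 3),
      diffusible = c(TRUE, FALSE, FALSE),
      mz = c(281.184, NA, NA), stringsAsFactors = FALSE)
    de <- data.frame(
      gene_id = c("A_u01", "A_u02"), strain = "A", partner = "C",
      day_min = min(config$rnaseq$days), day_max = max(config$days),
      lfc = c(2, -2), stringsAsFactors = FALSE)
  }
  planted_truth(producer_features = pf, de_genes = de)
}

# Colony radius truth: baseline radius, plus growth promotion of A by
# its partners (strongest from C) and inhibition of C next to A, the
# qualitative interaction pattern being emulated.
colony_radius <- function(focal, partner, base) {
  r <- base
  if (focal == "A" && partner != "A")
    r <- base * switch(partner, C = 1.8, B = 1.4, 1.25)
  if (focal == "C" && partner == "A") r <- base * 0.7
  r
}

#' Run the co-culture analysis pipeline end to end
#'
#' Executes the stages named in `config$stages` in dependency order on
#' synthetic data generated under the config seed, writing every tabular
#' output as TSV under `outdir` together with a JSON manifest of
#' parameters and MD5 hashes of all files written. Identical config and
#' seed give byte-identical outputs. Any stage error aborts the run with
#' the stage name.
#'
#' @param config a config list (merged over [default_config()]) or a
#'   YAML path.
#' @param outdir output directory.
#' @return the manifest, invisibly; all outputs are on disk.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config)) config <- read_config(config)
  else {
    config <- merge_config(default_config(), config)
    validate_config(config)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(x, name) {
    p <- file.path(outdir, name)
    write_tsv(x, p)
    files <<- c(files, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  st <- config$stages
  state <- list(config = config)

  state$design <- synth_design(config$strains, config$days,
                               config$replicates, seed = config$seed)
  truth <- default_truth(config)

  if ("simulate" %in% st || any(c("rnaseq", "enrichment") %in% st)) {
    state$genomes <- stage("simulate", do.call(gen_genomes, c(
      list(design = state$design), config$simulate,
      list(seed = child_seed(config$seed, 1)))))
    put(state$genomes$annotation, "genes.tsv")
  }
  if ("simulate" %in% st || "metabolomics" %in% st) {
    state$peaks <- stage("simulate", do.call(gen_peaktable, c(
      list(design = state$design, truth = truth),
      config$metabolomics[c("n_features", "n_noise_features", "noise_sd",
                            "drift_slope", "missing_rate", "qc_every",
                            "adduct_pairs")],
      list(seed = child_seed(config$seed, 2)))))
    p <- file.path(outdir, "peaks_raw.tsv")
    write_peak_table(state$peaks, p)
    files <- c(files, p, sub("\\.tsv$", "_samples.tsv", p))
  }

  if ("rnaseq" %in% st) {
    stage("rnaseq", {
      rcfg <- config$rnaseq
      rna_design <- synth_design(config$strains, rcfg$days,
                                 config$replicates, seed = config$seed)
      reads <- gen_reads(state$genomes, rna_design, truth,
                         depth = rcfg$depth, read_len = rcfg$read_len,
                         rrna_fraction = rcfg$rrna_fraction,
                         seed = child_seed(config$seed, 3))
      index <- build_reference_index(state$genomes, k = rcfg$k)
      sm <- rna_design$samples
      if (isTRUE(rcfg$multiplex_pairs)) {
        # one library per plate pair: X-Y pooled with its mirror Y-X
        libs <- list()
        for (i in seq_len(nrow(sm))) {
          s <- sm[i, ]
          if (s$focal < s$partner || s$focal == s$partner) {
            mirror <- sprintf("%s-%s_d%d_r%d", s$partner, s$focal,
                              s$day, s$replicate)
            members <- unique(c(s$sample_id,
                                if (s$focal != s$partner) mirror))
            libs[[sprintf("lib_%s", s$sample_id)]] <- members
          }
        }
        muxed <- multiplex_reads(reads, libs)
        cm <- deconvolve_libraries(muxed, index, rna_design,
                                   lib_samples = libs,
                                   min_kmer_fraction = rcfg$min_kmer_fraction,
                                   min_match_frac = rcfg$min_match_frac)
      } else {
        libs <- as.list(stats::setNames(names(reads$reads),
                                        names(reads$reads)))
        cm <- deconvolve_libraries(reads$reads, index, rna_design,
                                   lib_samples = libs,
                                   min_kmer_fraction = rcfg$min_kmer_fraction,
                                   min_match_frac = rcfg$min_match_frac)
      }
      put(data.frame(gene_id = rownames(cm$counts), cm$counts,
                     check.names = FALSE), "counts_raw.tsv")
      put(cm$accounting, "read_accounting.tsv")
      nrm <- normalized_counts(cm, pseudo_reference = TRUE)
      put(data.frame(gene_id = rownames(nrm), round(nrm, 4),
                     check.names = FALSE), "counts_normalized.tsv")
      tp <- tpm(cm)
      put(data.frame(gene_id = rownames(tp), round(tp, 2),
                     check.names = FALSE), "tpm.tsv")
      # Wald DE per focal strain and partner vs the axenic pairing
      de_all <- list()
      for (f in config$strains) for (p in setdiff(config$strains, f)) {
        cols <- sm$sample_id[sm$focal == f & sm$day == rcfg$test_day &
                               sm$partner %in% c(f, p)]
        sub <- cm$counts[grepl(paste0("^", f, "_"), rownames(cm$counts)),
                         cols, drop = FALSE]
        grp <- ifelse(sm$partner[match(cols, sm$sample_id)] == f,
                      "axenic", "paired")
        de <- differential_expression(sub, mode = "wald", group = grp,
                                      ref = "axenic",
                                      pseudo_reference = TRUE)
        de$focal <- f; de$partner <- p
        de_all[[paste(f, p)]] <- de
      }
      state$de <- do.call(rbind, de_all)
      put(state$de, "de_wald.tsv")
      # LRT across partner x day per focal strain
      lrt_all <- list()
      for (f in config$strains) {
        cols <- sm$sample_id[sm$focal == f]
        sub <- cm$counts[grepl(paste0("^", f, "_"), rownames(cm$counts)),
                         cols, drop = FALSE]
        meta <- sm[match(cols, sm$sample_id), ]
        lrt <- differential_expression(sub, samples = meta, mode = "lrt",
                                       pseudo_reference = TRUE)
        lrt$focal <- f
        lrt_all[[f]] <- lrt
      }
      state$lrt <- do.call(rbind, lrt_all)
      put(state$lrt, "de_lrt.tsv")
      state$counts <- cm
    })
  }

  if ("metabolomics" %in% st) {
    stage("metabolomics", {
      mcfg <- config$metabolomics
      proc <- preprocess_peaks(state$peaks,
                               min_present_frac = mcfg$min_present_frac,
                               blank_ratio = mcfg$blank_ratio,
                               rt_window = mcfg$rt_window,
                               min_corr = mcfg$min_corr, k = mcfg$knn_k,
                               lambda = mcfg$lambda)
      state$peaks_proc <- proc
      sel <- list()
      for (f in config$strains) for (p in setdiff(config$strains, f)) {
        att <- attribute_producers(proc, f, p, alpha = mcfg$alpha,
                                   lfc_min = mcfg$lfc_min)
        if (any(att$selected))
          sel[[paste(f, p)]] <- data.frame(
            feature_id = names(which(att$selected)), focal = f, partner = p,
            stringsAsFactors = FALSE)
      }
      state$selected <- if (length(sel)) do.call(rbind, sel)
        else data.frame(feature_id = character(), focal = character(),
                        partner = character(), stringsAsFactors = FALSE)
      put(state$selected, "metabolite_attribution.tsv")
      ann <- match_known_ions(proc, data.frame(
        name = "DFO-B", formula = "C25H48N6O8",
        adducts = "[M+H]+;[M+2H]2+", stringsAsFactors = FALSE))
      put(ann, "ion_annotation.tsv")
    })
  }

  if ("colonies" %in% st) {
    stage("colonies", {
      ccfg <- config$colonies
      px <- ccfg$image_px
      rim_px <- round(0.9 * px)
      rows <- list()
      img_i <- 0L
      for (f in config$strains) for (p in config$strains)
        for (r in seq_len(ccfg$n_images)) {
          img_i <- img_i + 1L
          rf <- colony_radius(f, p, ccfg$base_radius_px)
          rp <- colony_radius(p, f, ccfg$base_radius_px)
          gap <- rim_px * 0.18
          jitter <- with_seed(child_seed(config$seed, 100 + img_i),
                              stats::runif(2, 0.93, 1.07))
          plate <- gen_plate_image(px, px, data.frame(
            cx = c(px / 2 - gap, px / 2 + gap), cy = px / 2,
            radius = c(rf, rp) * jitter),
            plate_diameter_px = rim_px,
            seed = child_seed(config$seed, 500 + img_i))
          comp <- segment_colonies(plate$image, min_area_px = ccfg$min_area_px,
                                   roi_split_x = px / 2)
          cfac <- px_to_mm_factor(detect_plate_rim(plate$image),
                                  ccfg$plate_mm)
          left <- comp[comp$cx < px / 2, , drop = FALSE]
          if (nrow(left))
            rows[[img_i]] <- data.frame(
              image_id = sprintf("img_%s-%s_r%d", f, p, r), focal = f,
              partner = p, replicate = r, day = ccfg$day,
              area_px = left$area_px[1],
              area_mm2 = left$area_px[1] * cfac^2,
              stringsAsFactors = FALSE)
        }
      areas <- do.call(rbind, rows)
      state$areas <- areas
      put(areas, "colony_areas.tsv")
      cmp <- list()
      for (f in config$strains) {
        a <- areas[areas$focal == f, ]
        cc <- compare_areas(a$area_mm2, a$partner)
        cc$focal <- f
        cmp[[f]] <- cc
      }
      put(do.call(rbind, cmp), "colony_area_tests.tsv")
    })
  }

  if ("enrichment" %in% st && !is.null(state$lrt)) {
    stage("enrichment", {
      ecfg <- config$enrichment
      maps <- gen_annotation(rownames(state$counts$counts),
                             n_pathways = ecfg$n_pathways,
                             genes_per_pathway = ecfg$genes_per_pathway,
                             seed = child_seed(config$seed, 4))
      enr <- list()
      for (f in unique(state$lrt$focal)) for (dir in c("up", "down")) {
        q <- de_to_query(state$lrt[state$lrt$focal == f, ], dir)
        if (!length(q)) next
        e <- tryCatch(
          hypergeom_enrich(q, maps$gene2ko, maps$ko2path,
                           min_size = min(ecfg$min_size,
                                          ecfg$genes_per_pathway),
                           p_cut = ecfg$p_cut),
          warning = function(w) NULL)
        if (!is.null(e) && nrow(e)) {
          e$focal <- f; e$direction <- dir
          enr[[paste(f, dir)]] <- e
        }
      }
      out <- if (length(enr)) do.call(rbind, enr)
        else data.frame(pathway = character())
      put(out, "pathway_enrichment.tsv")
    })
  }

  if ("report" %in% st)
    state <- pipeline_report(state, outdir, put = put,
                             reg = function(p) files <<- c(files, p))

  manifest <- list(
    package_version = as.character(utils::packageVersion("coculture")),
    seed = config$seed, parameters = config,
    files = lapply(stats::setNames(files, basename(files)), function(p)
      unname(tools::md5sum(p))))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

# Figure-backing tables: colony box-plot data, z-scored heatmap of
# selected features, volcano table, target-ion trace. Each table also
# gets a plain base-graphics render next to it.
pipeline_report <- function(state, outdir, put, reg = function(p) p) {
  render <- function(name, w, h, expr) {
    p <- file.path(outdir, name)
    grDevices::png(p, width = w, height = h)
    on.exit(grDevices::dev.off(), add = TRUE)
    tryCatch(expr, error = function(e) graphics::plot.new())
    reg(p)
    p
  }
  if (!is.null(state$areas)) {
    put(state$areas[, c("focal", "partner", "replicate", "area_mm2")],
        "fig_box_areas.tsv")
    render("fig_box_areas.png", 640, 480, {
      a <- state$areas
      graphics::boxplot(area_mm2 ~ partner + focal, data = a,
                        las = 2, ylab = "colony area (mm2)",
                        main = "Focal colony area by partner")
    })
  }
  if (!is.null(state$selected) && nrow(state$selected) &&
      !is.null(state$peaks_proc)) {
    feats <- unique(state$selected$feature_id)
    M <- state$peaks_proc$intensity[feats, , drop = FALSE]
    bio <- state$peaks_proc$samples$role == "sample"
    Z <- row_zscore(M[, bio, drop = FALSE])
    put(data.frame(feature_id = rownames(Z), round(Z, 4),
                   check.names = FALSE), "fig_heatmap_z.tsv")
    render("fig_heatmap_z.png", 800, 400, {
      graphics::image(t(Z), axes = FALSE,
                      main = "Selected features (row Z-scores)")
    })
  }
  if (!is.null(state$de)) {
    v <- state$de
    v$flag <- !is.na(v$padj) & v$padj < 0.05 & abs(v$log2FC) > 2
    put(v[, c("focal", "partner", "gene_id", "log2FC", "pvalue", "padj",
              "flag")], "fig_volcano.tsv")
    render("fig_volcano.png", 640, 480, {
      graphics::plot(v$log2FC, -log10(v$pvalue),
                     col = ifelse(v$flag, "red", "grey40"), pch = 19,
                     xlab = "log2 fold change", ylab = "-log10 p",
                     main = "Paired vs axenic")
      graphics::abline(v = c(-2, 2), h = -log10(0.05), lty = 2)
    })
  }
  if (!is.null(state$peaks)) {
    ann <- match_known_ions(state$peaks, data.frame(
      name = "DFO-B", formula = "C25H48N6O8", adducts = "[M+2H]2+",
      stringsAsFactors = FALSE), tol_ppm = 10)
    if (nrow(ann)) {
      sm <- state$peaks$samples
      bio <- sm$role == "sample"
      tr <- data.frame(sm[bio, c("sample_id", "focal", "partner", "day")],
                       intensity = state$peaks$intensity[ann$feature_id[1],
                                                         bio])
      put(tr, "fig_target_ion_trace.tsv")
      render("fig_target_ion_trace.png", 800, 480, {
        cond <- interaction(tr$focal, tr$partner, sep = "-")
        graphics::boxplot(log2(tr$intensity) ~ cond, las = 2,
                          ylab = "log2 intensity",
                          main = "Target ion abundance by pairing")
      })
    }
  }
  state
}
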