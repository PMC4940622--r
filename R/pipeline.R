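pipeline_defaults <- function() {
  list(maf_min = 0.2, q = 0.99, permutations = 1000L, min_snps = 2L,
       top_k = 13L, traits = default_gwa_traits())
}

known_config_keys <- function() {
  list(
    top = c("paths", "settings", "seed", "verbosity"),
    paths = c("genotype", "annotation", "phenotype", "fold_change",
              "out_dir"),
    settings = names(pipeline_defaults())
  )
}

reject_unknown <- function(keys, known, where) {
  unknown <- setdiff(keys, known)
  if (length(unknown) == 0) return(invisible(NULL))
  hints <- vapply(unknown, function(k) {
    d <- utils::adist(k, known)
    if (min(d) <= 3) sprintf(" (did you mean '%s'?)", known[which.min(d)])
    else ""
  }, character(1))
  stop("unknown ", where, " key(s): ",
       paste0("'", unknown, "'", hints, collapse = ", "), call. = FALSE)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), rejects
#' unknown keys (with a nearest-key suggestion for likely typos), checks
#' ranges and input-file existence, and fills defaults (`maf_min` 0.2,
#' `permutations` 1000, `q` 0.99, `min_snps` 2, `top_k` 13, the six
#' standard traits), reporting every default applied.
#'
#' @param config Path to a YAML file, a YAML string, or a list.
#' @param check_paths Verify that input files exist (default TRUE).
#' @return Object of class `pipeline_config`.
#' @export
validate_config <- function(config, check_paths = TRUE) {
  if (is.character(config)) {
    raw <- if (length(config) == 1L && file.exists(config))
      yaml::read_yaml(config) else yaml::yaml.load(paste(config,
                                                         collapse = "\n"))
  } else if (is.list(config)) {
    raw <- config
  } else {
    stop("config must be a file path, YAML text, or a list", call. = FALSE)
  }
  known <- known_config_keys()
  reject_unknown(names(raw), known$top, "top-level")
  paths <- raw$paths %||% list()
  settings <- raw$settings %||% list()
  reject_unknown(names(paths), known$paths, "paths")
  reject_unknown(names(settings), known$settings, "settings")

  for (p in c("genotype", "annotation", "phenotype", "fold_change")) {
    if (is.null(paths[[p]])) {
      stop("missing required path: '", p, "'", call. = FALSE)
    }
    if (check_paths && !file.exists(paths[[p]])) {
      stop("input file for '", p, "' does not exist: ", paths[[p]],
           call. = FALSE)
    }
  }
  if (is.null(paths$out_dir)) stop("missing required path: 'out_dir'",
                                   call. = FALSE)

  defaults <- pipeline_defaults()
  for (k in names(defaults)) {
    if (is.null(settings[[k]])) {
      settings[[k]] <- defaults[[k]]
      message(sprintf("applying default %s = %s", k,
                      paste(format(defaults[[k]]), collapse = ", ")))
    }
  }
  if (settings$maf_min < 0 || settings$maf_min >= 0.5) {
    stop("settings$maf_min out of range [0, 0.5)", call. = FALSE)
  }
  if (settings$q <= 0 || settings$q > 1) {
    stop("settings$q out of range (0, 1]", call. = FALSE)
  }
  if (settings$permutations < 1) stop("settings$permutations must be >= 1",
                                      call. = FALSE)
  if (settings$min_snps < 1) stop("settings$min_snps must be >= 1",
                                  call. = FALSE)
  if (settings$top_k < 1) stop("settings$top_k must be >= 1", call. = FALSE)
  structure(list(paths = paths, settings = settings,
                 seed = as.integer(raw$seed %||% 1L),
                 verbosity = as.integer(raw$verbosity %||% 1L)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipe_log <- function(cfg, ...) {
  if (cfg$verbosity > 0) message(sprintf(...))
}

run_stage <- function(cfg, name, fun) {
  pipe_log(cfg, "[%s] starting", name)
  tryCatch(fun(), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading, trait-table construction, ANOVA +
#' heritability statistics, LS-mean trait matrix, ridge/HEM GWA with
#' permutation thresholds, and gene-level candidate calling with
#' condition-overlap analysis and expression-based prioritization. All
#' results are written under `cfg$paths$out_dir` together with a run
#' manifest (JSON) recording settings, seed, package version and an MD5
#' checksum of every output, so a rerun with the same config and seed
#' reproduces identical outputs.
#'
#' @param cfg A `pipeline_config` from [validate_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  s <- cfg$settings
  outputs <- character(0)
  note <- function(path) outputs <<- c(outputs, path)

  inputs <- run_stage(cfg, "load", function() {
    list(panel = read_genotype_tsv(cfg$paths$genotype),
         ann = read_annotation_gff3(cfg$paths$annotation),
         pheno = read_phenotype_tsv(cfg$paths$phenotype),
         fc = read_tsv_plain(cfg$paths$fold_change))
  })

  traits_tab <- run_stage(cfg, "traits", function() {
    tt <- build_trait_table(inputs$pheno)
    write_phenotype_tsv(tt, file.path(out, "trait_table.tsv"))
    note(file.path(out, "trait_table.tsv"))
    tt
  })

  stats_out <- run_stage(cfg, "stats", function() {
    res <- lapply(s$traits, function(tr) {
      an <- fit_anova(traits_tab, tr)
      h2 <- broad_sense_h2(traits_tab, tr)
      list(anova = an, h2 = h2)
    })
    names(res) <- s$traits
    an_all <- do.call(rbind, lapply(s$traits, function(tr) {
      cbind(trait = tr, as.data.frame(res[[tr]]$anova))
    }))
    write_tsv_plain(an_all, file.path(out, "anova.tsv"))
    note(file.path(out, "anova.tsv"))
    h2_all <- data.frame(
      trait = s$traits,
      H2 = vapply(res, function(r) r$h2$H2, numeric(1)),
      sigma_g2 = vapply(res, function(r) r$h2$sigma_g2, numeric(1)),
      sigma_e2 = vapply(res, function(r) r$h2$sigma_e2, numeric(1))
    )
    write_tsv_plain(h2_all, file.path(out, "heritability.tsv"))
    note(file.path(out, "heritability.tsv"))
    res
  })

  tm <- run_stage(cfg, "lsmeans", function() {
    tm <- build_trait_matrix(traits_tab, s$traits)
    write_phenotype_tsv(tm, file.path(out, "trait_matrix.tsv"))
    note(file.path(out, "trait_matrix.tsv"))
    tm
  })

  gwa <- run_stage(cfg, "gwa", function() {
    g <- run_gwa(tm, inputs$panel, traits = s$traits,
                 maf_min = s$maf_min, q = s$q, B = s$permutations,
                 seed = cfg$seed)
    write_tsv_plain(g$effects, file.path(out, "gwa_effects.tsv"))
    note(file.path(out, "gwa_effects.tsv"))
    thr <- lapply(g$results, function(per_cond) {
      lapply(per_cond, function(h) list(tau = h$tau, q = h$q, B = h$B,
                                        lambda = h$lambda,
                                        sigma_u2 = h$sigma_u2,
                                        sigma_e2 = h$sigma_e2))
    })
    jsonlite::write_json(list(settings = s, seed = cfg$seed,
                              thresholds = thr),
                         file.path(out, "gwa_thresholds.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note(file.path(out, "gwa_thresholds.json"))
    g
  })

  run_stage(cfg, "candidates", function() {
    cand_rows <- list()
    overlaps <- list()
    prio <- list()
    for (tr in names(gwa$results)) {
      sets <- list()
      for (cond in names(gwa$results[[tr]])) {
        slice <- gwa$effects[gwa$effects$trait == tr &
                               gwa$effects$condition == cond, ]
        counts <- assign_snps_to_genes(slice, inputs$ann)
        sets[[cond]] <- call_candidates(counts, s$min_snps, trait = tr,
                                        condition = cond)
        cand_rows[[paste(tr, cond)]] <- tibble(
          trait = tr, condition = cond,
          gene_id = sets[[cond]]$gene_id,
          n_sig_snps = sets[[cond]]$n_sig_snps,
          candidate = as.integer(sets[[cond]]$candidate)
        )
      }
      conds <- names(sets)
      ctrl <- conds[conds == "MS"]
      trt <- setdiff(conds, "MS")
      if (length(ctrl) == 1L && length(trt) >= 1L) {
        rep_ <- compare_conditions(sets[[ctrl]], sets[[trt[1L]]])
        overlaps[[tr]] <- list(
          counts = as.list(rep_$counts),
          unique_control = rep_$unique_control,
          unique_treated = rep_$unique_treated,
          shared = rep_$shared
        )
        pr <- suppressWarnings(prioritize_candidates(rep_, inputs$fc,
                                                     s$top_k))
        if (nrow(pr) > 0) prio[[tr]] <- cbind(trait = tr,
                                              as.data.frame(pr))
      }
    }
    write_tsv_plain(do.call(rbind, cand_rows),
                    file.path(out, "candidates.tsv"))
    note(file.path(out, "candidates.tsv"))
    jsonlite::write_json(overlaps, file.path(out, "overlaps.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note(file.path(out, "overlaps.json"))
    if (length(prio) > 0) {
      write_tsv_plain(do.call(rbind, prio),
                      file.path(out, "priority_genes.tsv"))
      note(file.path(out, "priority_genes.tsv"))
    }
    invisible(NULL)
  })

  manifest <- list(
    package = "allylgwa",
    version = as.character(utils::packageVersion("allylgwa")),
    seed = cfg$seed,
    settings = s,
    inputs = cfg$paths[c("genotype", "annotation", "phenotype",
                         "fold_change")],
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log(cfg, "[done] %d outputs in %s", length(outputs) + 1L, out)
  invisible(manifest)
}
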