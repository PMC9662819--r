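## Configuration-driven orchestration of the whole analysis. A single
## JSON config is the only source of parameters; stages read their
## inputs from the artifact directory so they can be run separately.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    paths = list(counts = NULL, pdb = NULL, sites = NULL,
                 imported_features = NULL),
    thresholds = list(read_threshold = 5, contact_cutoff = 8,
                      lri_min_sep = 10, ligand_cutoff = 5,
                      gnm_cutoff = 7.3, centrality_cutoff = 5),
    simulate = list(n_positions = 60L, n_hotspots = 8L,
                    p_dead_hotspot = 0.9, p_dead_other = 0.03,
                    mean_depth = 100, dropout_rate = 0.05),
    ml = list(hidden_units = 10L, learning_rate = 0.0007, epochs = 200L,
              cv_repeats = 2L, p_values = c(1L, 2L), top_k = 10L,
              ga_pool = 30L, ga_generations = 5L),
    stages = c("simulate", "score", "lri", "features", "importance")
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a JSON config (or takes a list), fills in every default,
#' rejects unknown keys, and checks that all referenced input paths
#' exist. All problems are reported in a single aggregated error.
#'
#' @param config Path to a JSON file or a named list.
#' @return The fully resolved config (class `run_config`) with a
#'   `config_hash` attribute.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- pipeline_defaults()
  problems <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown top-level key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  for (sec in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[sec]]) && !is.null(names(defaults[[sec]]))) {
      bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
      if (length(bad)) {
        problems <- c(problems, sprintf("unknown key(s) in '%s': %s", sec,
                                        paste(bad, collapse = ", ")))
      }
    }
  }
  merged <- utils::modifyList(defaults, config, keep.null = TRUE)
  for (p in names(merged$paths)) {
    path <- merged$paths[[p]]
    if (!is.null(path) && !file.exists(path)) {
      problems <- c(problems, sprintf("paths$%s does not exist: %s", p, path))
    }
  }
  if (length(problems)) {
    stopf("invalid configuration:\n- %s", paste(problems, collapse = "\n- "))
  }
  merged$seed <- assert_count(merged$seed, "seed", min = 0L)
  attr(merged, "config_hash") <- config_hash(merged)
  class(merged) <- "run_config"
  merged
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  unname(tools::md5sum(tmp))
}

provenance_header <- function(config, stage) {
  sprintf("# allohot stage=%s seed=%d config_hash=%s",
          stage, config$seed, attr(config, "config_hash"))
}

write_artifact_tsv <- function(df, file, config, stage) {
  con <- file(file, "w")
  writeLines(provenance_header(config, stage), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(file)
}

read_artifact_tsv <- function(file) {
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}

write_artifact_json <- function(x, file, config, stage) {
  x <- c(list(provenance = list(stage = stage, seed = config$seed,
                                config_hash = attr(config, "config_hash"))),
         x)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Run pipeline stages
#'
#' Executes the requested stages in dependency order
#' (`simulate -> score -> lri/features -> importance -> select`),
#' writing every artifact with a provenance header (stage, seed, config
#' hash) into `outdir`. When a stage's upstream artifact is missing the
#' run stops naming the stage to run first. With fixed config and seed
#' the artifact set is bit-reproducible.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param stages Character vector of stages to run; defaults to the
#'   config's `stages`.
#' @param outdir Artifact directory (created if needed).
#' @return The artifact directory, invisibly; a named list of written
#'   files in attribute `"artifacts"`.
#' @export
run_pipeline <- function(config = list(), stages = NULL, outdir) {
  config <- validate_config(if (inherits(config, "run_config"))
    unclass(config) else config)
  stages <- stages %||% config$stages
  order_all <- c("simulate", "score", "lri", "features", "importance",
                 "select")
  bad <- setdiff(stages, order_all)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- order_all[order_all %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(outdir, name)
  need <- function(file, producer) {
    if (!file.exists(file)) {
      stopf("missing artifact %s: run stage '%s' first", file, producer)
    }
    file
  }
  written <- character(0)
  thr <- config$thresholds

  if ("simulate" %in% stages) {
    sim <- config$simulate
    scen <- dms_scenario(
      n_positions = sim$n_positions,
      planted_hotspots = planted_positions(sim$n_positions,
                                           sim$n_hotspots, config$seed),
      p_dead_hotspot = sim$p_dead_hotspot,
      p_dead_other = sim$p_dead_other, mean_depth = sim$mean_depth,
      dropout_rate = sim$dropout_rate,
      seed = child_seed(config$seed, 1))
    counts <- generate_dms_counts(scen)
    write_artifact_tsv(counts, art("counts.tsv"), config, "simulate")
    struct <- generate_structure(sim$n_positions,
                                 seed = child_seed(config$seed, 2))
    write_structure_pdb(struct, art("structure.pdb"))
    write_sites_tsv(struct$ligand_sites, art("ligand_sites.tsv"), "ligand")
    write_sites_tsv(struct$dna_sites, art("dna_sites.tsv"), "dna")
    write_artifact_tsv(attr(counts, "truth"), art("truth.tsv"), config,
                       "simulate")
    write_artifact_tsv(
      data.frame(position = scen$planted_hotspots),
      art("planted_hotspots.tsv"), config, "simulate")
    written <- c(written, art("counts.tsv"), art("structure.pdb"))
  }

  if ("score" %in% stages) {
    counts_file <- config$paths$counts %||%
      need(art("counts.tsv"), "simulate")
    counts <- data.table::as.data.table(read_artifact_tsv(counts_file))
    res <- score_pipeline(counts, read_threshold = thr$read_threshold)
    write_artifact_tsv(
      cbind(res$scores,
            is_hotspot = res$scores$position %in%
              res$hotspots$hotspot_positions),
      art("positions.tsv"), config, "score")
    write_artifact_tsv(
      data.frame(position = res$hotspots$hotspot_positions),
      art("hotspots.tsv"), config, "score")
    rep <- mutation_property_comparison(res$calls)
    write_artifact_json(list(
      q3_threshold = res$hotspots$q3_threshold,
      n_hotspots = length(res$hotspots$hotspot_positions),
      enrichment = if (rep$computable) {
        list(composition = rep$composition, properties = rep$properties)
      } else list(computable = FALSE)),
      art("scoring.json"), config, "score")
    written <- c(written, art("positions.tsv"), art("hotspots.tsv"))
  }

  if ("lri" %in% stages || "features" %in% stages) {
    pdb_file <- config$paths$pdb %||% need(art("structure.pdb"), "simulate")
    struct <- read_structure(pdb_file)
    sites <- if (!is.null(config$paths$sites)) {
      read_sites_tsv(config$paths$sites)
    } else {
      c(read_sites_tsv(need(art("ligand_sites.tsv"), "simulate")),
        read_sites_tsv(need(art("dna_sites.tsv"), "simulate")))
    }
    hotspots <- read_artifact_tsv(need(art("hotspots.tsv"), "score"))$position
  }

  if ("lri" %in% stages) {
    cm <- contact_map(struct, cutoff = thr$contact_cutoff)
    lri <- extract_lri(cm, min_sep = thr$lri_min_sep)
    cl <- cluster_lri(lri, k_range = 2:min(8, nrow(lri) - 1),
                      seed = child_seed(config$seed, 3))
    pairs <- cm$pairs
    pairs$is_lri <- paste(pairs$i, pairs$j) %in% paste(lri$i, lri$j)
    pairs$cluster <- NA_integer_
    pairs$cluster[pairs$is_lri] <- cl$assignment
    write_artifact_tsv(pairs, art("contact_map.tsv"), config, "lri")
    ranking <- rank_clusters(cl, hotspots, cm$monomer_length)
    write_artifact_tsv(ranking, art("cluster_ranking.tsv"), config, "lri")
    written <- c(written, art("contact_map.tsv"), art("cluster_ranking.tsv"))
  }

  if ("features" %in% stages) {
    seq_len_mono <- max(struct$atoms$resno)
    sequence <- aa_from_resid(struct$atoms)
    imported <- if (!is.null(config$paths$imported_features)) {
      read_imported_features(config$paths$imported_features)
    } else zero_imported_columns(seq_len_mono)
    fm <- assemble_feature_matrix(
      struct, sequence = sequence, hotspots = hotspots,
      imported = imported, dna_sites = sites$dna,
      ligand_sites = sites$ligand, gnm_cutoff = thr$gnm_cutoff,
      centrality_cutoff = thr$centrality_cutoff)
    write_artifact_tsv(fm, art("feature_matrix.tsv"), config, "features")
    written <- c(written, art("feature_matrix.tsv"))
  }

  if ("importance" %in% stages) {
    fm <- read_artifact_tsv(need(art("feature_matrix.tsv"), "features"))
    imp <- rank_features(fm)
    write_artifact_tsv(imp$table, art("importance.tsv"), config,
                       "importance")
    written <- c(written, art("importance.tsv"))
  }

  if ("select" %in% stages) {
    fm <- read_artifact_tsv(need(art("feature_matrix.tsv"), "features"))
    ml <- config$ml
    spec <- nn_spec(hidden_units = ml$hidden_units,
                    learning_rate = ml$learning_rate,
                    epochs = ml$epochs)
    results <- list()
    for (p in ml$p_values) {
      results[[as.character(p)]] <- if (p <= 3) {
        exhaustive_search(fm, p, spec = spec, n_repeats = ml$cv_repeats,
                          seed = child_seed(config$seed, 10 + p))
      } else {
        ga_select(fm, p, spec = spec, pool_size = ml$ga_pool,
                  generations = ml$ga_generations,
                  n_repeats = ml$cv_repeats,
                  seed = child_seed(config$seed, 10 + p))$archive
      }
    }
    freq <- feature_frequency(results, top_k = ml$top_k)
    best <- lapply(results, function(r) {
      list(combo = r$combo[[1]], fitness = r$fitness[1])
    })
    write_artifact_json(list(best = best, mean_f1_top = freq$mean_f1,
                             frequency = freq$frequency),
                        art("selection.json"), config, "select")
    written <- c(written, art("selection.json"))
  }

  out <- outdir
  attr(out, "artifacts") <- written
  invisible(out)
}

## helper: planted hotspot positions spread over the mutagenized range
planted_positions <- function(n_positions, n_hotspots, seed) {
  with_seed(child_seed(seed, 99), sort(sample(2:n_positions, n_hotspots)))
}

## monomer sequence from chain A residue names
aa_from_resid <- function(atoms) {
  chains <- sort(unique(atoms$chain))
  a <- atoms[atoms$chain == chains[1] & atoms$elety == "CA", ]
  a <- a[order(a$resno), ]
  code <- stats::setNames(names(AA3), AA3)
  unname(code[a$resid])
}
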