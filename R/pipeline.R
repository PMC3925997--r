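#' Run the comparative co-expression pipeline
#'
#' Orchestrates simulate -> infer -> properties -> motifs -> compare from a
#' single configuration, writing all stage outputs and a manifest with file
#' checksums, stage parameters, seeds and package version. Deterministic
#' stages are byte-identical on rerun with the same configuration.
#'
#' The configuration is a list (or a YAML/JSON file) with elements:
#' \describe{
#'   \item{simulation}{arguments for [scenario_spec()]; if absent, `species`
#'     must map species labels to lists with `expression`, `tfs`, `go`
#'     paths, plus top-level `orthologs` (and optional `bitscores`) paths.}
#'   \item{thresholds}{numeric CLR thresholds (default c(2, 4)).}
#'   \item{n_rand}{randomizations for motif Z-scores (default 20).}
#'   \item{fdr}{FDR level for neighbourhood classification (default 0.05).}
#'   \item{seed}{integer master seed (default 1).}
#'   \item{out_dir}{output directory.}
#'   \item{stages}{subset of c("simulate","infer","properties","motifs",
#'     "compare"); defaults to all applicable.}
#' }
#'
#' @param config list or path to a YAML/JSON configuration file.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  thresholds <- config$thresholds %||% c(2, 4)
  n_rand <- config$n_rand %||% 20L
  fdr <- config$fdr %||% 0.05
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  stages <- config$stages %||%
    c(if (!is.null(config$simulation)) "simulate",
      "infer", "properties", "motifs", "compare")
  warnings_log <- character(0)
  note_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  files <- character(0)
  stage_log <- list()
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(withCallingHandlers(fn(), warning = note_warning),
                    error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stage_log[[name]] <<- list(seconds = as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  # ---- validation ----------------------------------------------------
  if (is.null(config$simulation)) {
    if (is.null(config$species) || is.null(config$orthologs)) {
      stop("config needs either a 'simulation' block or 'species' inputs plus 'orthologs'")
    }
    paths <- c(unlist(lapply(config$species, function(s) {
      c(s$expression, s$tfs, s$go)
    })), config$orthologs, config$bitscores)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- simulate ------------------------------------------------------
  study <- NULL
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% seed
    spec <- do.call(scenario_spec, sim_args)
    study <- simulate_study(spec)
    if ("simulate" %in% stages) {
      files <- c(files, run_stage("simulate", function() {
        write_study(study, file.path(out_dir, "simulate"))
      }))
    }
  }

  # ---- load inputs ---------------------------------------------------
  if (!is.null(study)) {
    expr <- study$expression
    tfs <- study$tfs
    go <- study$go
    map <- study$orthologs
  } else {
    expr <- lapply(names(config$species), function(sp) {
      read_expression(config$species[[sp]]$expression, sp)
    })
    names(expr) <- names(config$species)
    tfs <- lapply(config$species, function(s) read_tf_list(s$tfs))
    go <- lapply(config$species, function(s) read_go_map(s$go))
    map <- read_ortholog_groups(config$orthologs, config$bitscores)
  }
  species <- names(expr)

  # ---- infer ---------------------------------------------------------
  nets <- list()
  if (any(c("infer", "properties", "motifs", "compare") %in% stages)) {
    run_stage("infer", function() {
      dir.create(file.path(out_dir, "infer"), showWarnings = FALSE)
      for (sp in species) {
        mi <- mi_matrix(expr[[sp]])
        clr <- clr_transform(mi)
        nets[[sp]] <<- list()
        for (th in thresholds) {
          net <- build_network(clr, th, tfs[[sp]])
          nets[[sp]][[as.character(th)]] <<- net
          if ("infer" %in% stages) {
            f <- file.path(out_dir, "infer", sprintf("%s_t%g_edges.tsv", sp, th))
            write_network(net, f)
            files <<- c(files, f)
          }
        }
      }
      NULL
    })
  }

  # ---- properties ----------------------------------------------------
  if ("properties" %in% stages) {
    run_stage("properties", function() {
      dir.create(file.path(out_dir, "properties"), showWarnings = FALSE)
      for (sp in species) {
        for (th in thresholds) {
          net <- nets[[sp]][[as.character(th)]]
          cent <- compute_centralities(net, "coexpression")
          f <- file.path(out_dir, "properties",
                         sprintf("%s_t%g_centralities.tsv", sp, th))
          utils::write.table(cent, f, sep = "\t", quote = FALSE, row.names = FALSE)
          files <<- c(files, f)
          fit <- tryCatch(fit_degree_distribution(net), error = function(e) NULL)
          if (!is.null(fit)) {
            f <- file.path(out_dir, "properties",
                           sprintf("%s_t%g_degree_fit.tsv", sp, th))
            utils::write.table(
              data.frame(classification = fit$classification,
                         alpha = fit$alpha, xmin = fit$xmin,
                         lambda = fit$lambda,
                         loglik_powerlaw = fit$loglik_powerlaw,
                         loglik_poisson = fit$loglik_poisson),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
            files <<- c(files, f)
          }
          stats_tab <- subnetwork_statistics(net, go[[sp]])
          f <- file.path(out_dir, "properties",
                         sprintf("%s_t%g_subnetworks.tsv", sp, th))
          utils::write.table(stats_tab, f, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          files <<- c(files, f)
        }
      }
      NULL
    })
  }

  # ---- motifs --------------------------------------------------------
  if ("motifs" %in% stages) {
    run_stage("motifs", function() {
      dir.create(file.path(out_dir, "motifs"), showWarnings = FALSE)
      catalog <- enumerate_motif_classes(3)
      th <- as.character(thresholds[1])
      for (sp in species) {
        mz <- motif_zscores(nets[[sp]][[th]], go[[sp]], catalog,
                            n_rand = n_rand, seed = child_seed(seed, sp))
        f <- file.path(out_dir, "motifs", sprintf("%s_motif_z.tsv", sp))
        utils::write.table(mz, f, sep = "\t", quote = FALSE, row.names = FALSE)
        files <<- c(files, f)
      }
      NULL
    })
  }

  # ---- compare -------------------------------------------------------
  if ("compare" %in% stages && length(species) >= 2) {
    run_stage("compare", function() {
      dir.create(file.path(out_dir, "compare"), showWarnings = FALSE)
      for (th in as.character(thresholds)) {
        for (s1 in species) {
          for (s2 in setdiff(species, s1)) {
            tst <- neighbourhood_tests(nets[[s1]][[th]], nets[[s2]][[th]],
                                       map, s1, s2)
            if (nrow(tst) == 0) next
            rep_ <- classify_genes(tst, fdr)
            base <- sprintf("%s_vs_%s_t%s", s1, s2, th)
            f <- file.path(out_dir, "compare", paste0(base, "_tests.tsv"))
            utils::write.table(rep_$tests, f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            files <<- c(files, f)
            f <- file.path(out_dir, "compare", paste0(base, "_genes.tsv"))
            utils::write.table(rep_$genes, f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            files <<- c(files, f)
            lc <- link_conservation(nets[[s1]][[th]], nets[[s2]][[th]],
                                    map, s1, s2)
            summary <- list(
              comparison = base,
              n_eligible = nrow(rep_$genes),
              category_counts = as.list(rep_$counts),
              fraction_conserved = unname(
                (rep_$counts["Conserved"] + rep_$counts["Conserved-and-Diverged"]) /
                  max(1, nrow(rep_$genes))),
              link_conservation = lc$fraction,
              n_links = lc$n_links
            )
            f <- file.path(out_dir, "compare", paste0(base, "_summary.json"))
            jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE)
            files <<- c(files, f)
          }
        }
      }
      NULL
    })
  }

  # ---- manifest ------------------------------------------------------
  files <- unique(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("comparex")),
    seed = seed,
    parameters = list(thresholds = thresholds, n_rand = n_rand, fdr = fdr),
    config = config[setdiff(names(config), "out_dir")],
    stages = stage_log,
    warnings = warnings_log,
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
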