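#' Scenario specification for synthetic multi-species expression data
#'
#' Defines the generative conditions for a planted multi-species co-expression
#' study: per-species expression matrices with latent-factor modules, ortholog
#' maps with labelled conserved / diverged / unrelated pairs, duplicated
#' paralogs, transcription-factor annotations and per-module GO terms. The
#' generator is the ground-truth counterpart of a real microarray compendium:
#' genes in the same module share a per-sample latent factor, so module
#' membership is recoverable by co-expression, and cross-species module
#' identity defines neighbourhood conservation.
#'
#' @param species_names character vector of species labels (>= 1; >= 2 for
#'   [simulate_study()]).
#' @param n_genes genes per species (nominal; paralog duplication can add a
#'   few genes in non-reference species).
#' @param n_samples samples per species.
#' @param n_modules number of co-expression modules.
#' @param module_size_range integer pair (min, max) module size.
#' @param fraction_conserved,fraction_diverged,fraction_unrelated class
#'   proportions for ortholog pairs of module genes; must sum to 1.
#' @param duplication_rate proportion of module genes whose ortholog is
#'   duplicated into one conserved (`_a`) and one diverged (`_b`) paralog copy.
#' @param tf_fraction proportion of genes flagged as transcription factors;
#'   one designated TF per module, the remainder placed at random.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   log-scale expression values.
#' @param seed integer seed; all generator output is a pure function of the
#'   spec including this seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(species_names = c("ath", "pop", "osa"),
                          n_genes = 300L,
                          n_samples = 100L,
                          n_modules = 4L,
                          module_size_range = c(65L, 85L),
                          fraction_conserved = 0.85,
                          fraction_diverged = 0.10,
                          fraction_unrelated = 0.05,
                          duplication_rate = 0.10,
                          tf_fraction = 0.1,
                          noise_sd = 0.5,
                          seed = 1L) {
  stopifnot(length(species_names) >= 1, !anyDuplicated(species_names),
            n_genes >= 1, n_samples >= 1, n_modules >= 1,
            length(module_size_range) == 2,
            module_size_range[1] >= 2,
            module_size_range[1] <= module_size_range[2])
  fr <- c(fraction_conserved, fraction_diverged, fraction_unrelated)
  if (any(fr < 0 | fr > 1)) stop("ortholog class fractions must be in [0,1]")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("fraction_conserved + fraction_diverged + fraction_unrelated must equal 1")
  }
  stopifnot(duplication_rate >= 0, duplication_rate <= 1,
            tf_fraction >= 0, tf_fraction <= 1, noise_sd >= 0)
  if (n_modules * module_size_range[1] > n_genes) {
    stop("module sizes exceed n_genes: ", n_modules, " modules of at least ",
         module_size_range[1], " genes do not fit in ", n_genes, " genes")
  }
  structure(
    list(species_names = species_names, n_genes = as.integer(n_genes),
         n_samples = as.integer(n_samples), n_modules = as.integer(n_modules),
         module_size_range = as.integer(module_size_range),
         fraction_conserved = fraction_conserved,
         fraction_diverged = fraction_diverged,
         fraction_unrelated = fraction_unrelated,
         duplication_rate = duplication_rate, tf_fraction = tf_fraction,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Synthetic study scenario:", length(x$species_names), "species (",
      paste(x$species_names, collapse = ", "), ")\n")
  cat("  ", x$n_genes, "genes x", x$n_samples, "samples;", x$n_modules,
      "modules of", x$module_size_range[1], "-", x$module_size_range[2], "genes\n")
  cat("   ortholog classes: conserved", x$fraction_conserved, "/ diverged",
      x$fraction_diverged, "/ unrelated", x$fraction_unrelated,
      "; duplication rate", x$duplication_rate, "\n")
  cat("   tf_fraction", x$tf_fraction, "; noise_sd", x$noise_sd,
      "; seed", x$seed, "\n")
  invisible(x)
}

# Deterministic study layout: gene tables per species (module, TF flag,
# paralog copy labels), ortholog pairs with planted classes, bit-scores and
# GO annotations. Expression draws happen later, per species.
scenario_layout <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(child_seed(spec$seed, "layout"), {
    ref <- spec$species_names[1]
    # module sizes are drawn from the range with P(s) proportional to
    # s^-2.5: co-expression cluster sizes in real networks are heavy-tailed
    # (many small tight clusters, few large diffuse ones); over a narrow
    # range the law is close to uniform
    size_support <- seq(spec$module_size_range[1], spec$module_size_range[2])
    sizes <- if (length(size_support) == 1L) {
      rep(size_support, spec$n_modules)
    } else {
      size_w <- size_support^(-2.5)
      sample(size_support, spec$n_modules, replace = TRUE,
             prob = size_w / sum(size_w))
    }
    while (sum(sizes) > spec$n_genes) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
    ref_genes <- sprintf("%s_g%d", ref, seq_len(spec$n_genes))
    module <- rep(NA_integer_, spec$n_genes)
    idx <- sample.int(spec$n_genes)   # random placement of modules
    pos <- 1L
    for (m in seq_len(spec$n_modules)) {
      module[idx[pos:(pos + sizes[m] - 1L)]] <- m
      pos <- pos + sizes[m]
    }
    genes <- list()
    genes[[ref]] <- data.frame(species = ref, gene = ref_genes, module = module,
                               copy = NA_character_, stringsAsFactors = FALSE)

    pairs <- NULL
    for (sp in setdiff(spec$species_names, ref)) {
      counter <- 0L
      new_id <- function(suffix = "") {
        counter <<- counter + 1L
        sprintf("%s_g%d%s", sp, counter, suffix)
      }
      rows <- list()
      prs <- list()
      for (i in seq_len(spec$n_genes)) {
        m <- module[i]
        if (is.na(m)) next   # background genes have no orthologs
        g <- ref_genes[i]
        if (stats::runif(1) < spec$duplication_rate) {
          m2 <- sample(setdiff(seq_len(spec$n_modules), m), 1L)
          ga <- new_id("_a"); gb <- new_id("_b")
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, gene = c(ga, gb), module = c(m, m2),
            copy = c("a", "b"), stringsAsFactors = FALSE)
          prs[[length(prs) + 1L]] <- data.frame(
            gene_a = g, species_b = sp, gene_b = c(ga, gb),
            class = c("conserved", "diverged"), copy = c("a", "b"),
            duplicated = TRUE, stringsAsFactors = FALSE)
        } else {
          cls <- sample(c("conserved", "diverged", "unrelated"), 1L,
                        prob = c(spec$fraction_conserved, spec$fraction_diverged,
                                 spec$fraction_unrelated))
          if (cls == "unrelated") next
          m_target <- if (cls == "conserved") m else {
            sample(setdiff(seq_len(spec$n_modules), m), 1L)
          }
          gn <- new_id()
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, gene = gn, module = m_target,
            copy = NA_character_, stringsAsFactors = FALSE)
          prs[[length(prs) + 1L]] <- data.frame(
            gene_a = g, species_b = sp, gene_b = gn, class = cls,
            copy = NA_character_, duplicated = FALSE, stringsAsFactors = FALSE)
        }
      }
      tab <- do.call(rbind, rows)
      # pad with unrelated background genes up to the nominal gene count
      n_pad <- spec$n_genes - nrow(tab)
      if (n_pad > 0) {
        pad <- data.frame(species = sp,
                          gene = vapply(seq_len(n_pad), function(i) new_id(), ""),
                          module = NA_integer_, copy = NA_character_,
                          stringsAsFactors = FALSE)
        tab <- rbind(tab, pad)
      }
      genes[[sp]] <- tab
      pairs <- rbind(pairs, do.call(rbind, prs))
    }

    # TFs: one designated regulator per module plus random extras
    tfs <- lapply(genes, function(tab) {
      designated <- vapply(seq_len(spec$n_modules), function(m) {
        memb <- tab$gene[!is.na(tab$module) & tab$module == m]
        if (length(memb) == 0) NA_character_ else sample(memb, 1L)
      }, "")
      designated <- designated[!is.na(designated)]
      target <- ceiling(spec$tf_fraction * nrow(tab))
      extra <- setdiff(tab$gene, designated)
      n_extra <- max(0L, target - length(designated))
      c(designated, if (n_extra > 0) sample(extra, min(n_extra, length(extra))))
    })

    # ortholog groups: one group per reference gene with partners; pairs
    # involving the same reference gene collapse into a single group
    members <- NULL
    bitrows <- NULL
    higher_copy <- NULL
    if (!is.null(pairs)) {
      grp_ids <- stats::setNames(sprintf("ORTHO%05d", seq_along(unique(pairs$gene_a))),
                                 unique(pairs$gene_a))
      members <- rbind(
        data.frame(group = grp_ids[unique(pairs$gene_a)], species = ref,
                   gene = unique(pairs$gene_a), stringsAsFactors = FALSE),
        data.frame(group = grp_ids[pairs$gene_a], species = pairs$species_b,
                   gene = pairs$gene_b, stringsAsFactors = FALSE)
      )
      # bit-scores: base 200 + N(0,10); for duplicated genes a fair coin
      # decides whether the *diverged* copy outranks the conserved one, so
      # sequence similarity is uninformative about regulatory conservation
      sc <- 200 + stats::rnorm(nrow(pairs), 0, 10)
      dup_genes <- unique(pairs$gene_a[pairs$duplicated])
      hc <- character(0)
      for (g in dup_genes) {
        for (sp in unique(pairs$species_b[pairs$gene_a == g & pairs$duplicated])) {
          ia <- which(pairs$gene_a == g & pairs$species_b == sp & pairs$copy == "a")
          ib <- which(pairs$gene_a == g & pairs$species_b == sp & pairs$copy == "b")
          diverged_higher <- stats::runif(1) < 0.5
          lohi <- sort(sc[c(ia, ib)])
          if (diverged_higher) {
            sc[ib] <- lohi[2]; sc[ia] <- lohi[1]
          } else {
            sc[ia] <- lohi[2]; sc[ib] <- lohi[1]
          }
          hc <- c(hc, stats::setNames(if (diverged_higher) "b" else "a",
                                      paste(g, sp, sep = "|")))
        }
      }
      higher_copy <- hc
      bitrows <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                            score = sc, stringsAsFactors = FALSE)
    }

    # GO annotation: one term per module (shared ids across species) plus a
    # background term carried by every gene
    go <- lapply(genes, function(tab) {
      mod_rows <- tab[!is.na(tab$module), , drop = FALSE]
      rbind(
        data.frame(gene = mod_rows$gene,
                   term = sprintf("GO:%07d", mod_rows$module),
                   stringsAsFactors = FALSE),
        data.frame(gene = tab$gene, term = "GO:0099999", stringsAsFactors = FALSE)
      )
    })

    list(genes = genes, pairs = pairs, members = members, bitscores = bitrows,
         higher_bitscore_copy = higher_copy, tfs = tfs, go = go,
         module_sizes = sizes)
  })
}

#' Simulate a per-species expression matrix
#'
#' Draws the latent-factor expression model for one species of a scenario:
#' each module has a per-sample latent factor z ~ N(0,1); a module gene's
#' value is loading * z + N(0, noise_sd) with loadings drawn U(0.5, 1.5);
#' background genes follow the same model with a private latent factor, so
#' their profiles are independent of everything else. Deterministic given the
#' scenario seed.
#'
#' @param spec a [scenario_spec()].
#' @param species one of `spec$species_names`.
#' @return An `expression_matrix` (genes x samples) for that species.
#' @export
simulate_expression <- function(spec, species) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!species %in% spec$species_names) {
    stop("unknown species '", species, "'")
  }
  layout <- scenario_layout(spec)
  tab <- layout$genes[[species]]
  n <- nrow(tab)
  with_seed(child_seed(spec$seed, paste0("expr_", species)), {
    loadings <- stats::runif(n, 0.5, 1.5)
    factors <- matrix(stats::rnorm(spec$n_modules * spec$n_samples),
                      spec$n_modules, spec$n_samples)
    vals <- matrix(0, n, spec$n_samples)
    bg <- which(is.na(tab$module))
    if (length(bg) > 0) {
      vals[bg, ] <- matrix(stats::rnorm(length(bg) * spec$n_samples),
                           length(bg), spec$n_samples)
    }
    inm <- which(!is.na(tab$module))
    if (length(inm) > 0) vals[inm, ] <- factors[tab$module[inm], , drop = FALSE]
    vals <- vals * loadings
    if (spec$noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(n * spec$n_samples, 0, spec$noise_sd),
                            n, spec$n_samples)
    }
    rownames(vals) <- tab$gene
    colnames(vals) <- sprintf("s%d", seq_len(spec$n_samples))
    expression_matrix(vals, species)
  })
}

#' Simulate a complete multi-species study
#'
#' Generates everything the comparative pipeline consumes: per-species
#' expression matrices, an ortholog map with bit-scores, TF lists, GO
#' annotations, and the planted ground truth. Conserved ortholog pairs sit in
#' matching co-expression modules across species; diverged pairs sit in
#' non-matching modules; unrelated genes have no ortholog. A duplicated gene
#' receives one conserved (`_a`) and one diverged (`_b`) paralog copy in each
#' other species, and with probability 0.5 the diverged copy is assigned the
#' higher BLAST bit-score.
#'
#' @param spec a [scenario_spec()] with at least two species.
#' @return A list with elements `expression` (named list of
#'   `expression_matrix`), `orthologs` (an [ortholog_map()]), `tfs` (named
#'   list of character vectors), `go` (named list of data.frames with columns
#'   gene, term), and `truth` (list with `pairs`, `genes`,
#'   `higher_bitscore_copy`).
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (length(spec$species_names) < 2) stop("simulate_study needs >= 2 species")
  layout <- scenario_layout(spec)
  expr <- lapply(spec$species_names, function(sp) simulate_expression(spec, sp))
  names(expr) <- spec$species_names
  map <- ortholog_map(layout$members %||% data.frame(group = character(0),
                                                     species = character(0),
                                                     gene = character(0)),
                      layout$bitscores)
  genes_tab <- do.call(rbind, layout$genes)
  rownames(genes_tab) <- NULL
  genes_tab$tf <- mapply(function(g, sp) g %in% layout$tfs[[sp]],
                         genes_tab$gene, genes_tab$species)
  list(
    expression = expr,
    orthologs = map,
    tfs = layout$tfs,
    go = layout$go,
    truth = list(pairs = layout$pairs, genes = genes_tab,
                 higher_bitscore_copy = layout$higher_bitscore_copy,
                 module_sizes = layout$module_sizes)
  )
}

#' Write a simulated study to disk
#'
#' Writes every component in the same plain-text dialects the readers in this
#' package accept: expression TSVs, an OrthoMCL-style `groups.txt`, a
#' bit-score TSV, per-species TF lists and GO maps, plus a ground-truth TSV.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (sp in names(study$expression)) {
    f <- file.path(dir, paste0("expression_", sp, ".tsv"))
    write_expression(study$expression[[sp]], f)
    files <- c(files, f)
    f <- file.path(dir, paste0("tfs_", sp, ".txt"))
    write_tf_list(study$tfs[[sp]], f)
    files <- c(files, f)
    f <- file.path(dir, paste0("go_", sp, ".tsv"))
    write_go_map(study$go[[sp]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "groups.txt")
  write_ortholog_groups(study$orthologs, f,
                        bitscore_path = file.path(dir, "bitscores.tsv"))
  files <- c(files, f, file.path(dir, "bitscores.tsv"))
  f <- file.path(dir, "ground_truth_pairs.tsv")
  utils::write.table(study$truth$pairs, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "ground_truth_genes.tsv")
  utils::write.table(study$truth$genes, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
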