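#' Pipeline run configuration
#'
#' @param libraries Named list, one entry per library. Each entry is a
#'   list with `organism` (`"bacteria"` or `"yeast"`) and `rounds`, a
#'   character vector of FASTQ/FASTA paths ordered round 0, 1, ...
#' @param outdir Output directory.
#' @param min_len Read-length filter in bp (default 400).
#' @param strict_len Keep only reads strictly longer than `min_len`.
#' @param anchors An [anchor_config()] (or a list of its arguments).
#' @param top_clusters Top-N clonotypes for homology clustering (100).
#' @param top_codon Top-N clonotypes for rare-codon statistics (10).
#' @param cluster_threshold Single-linkage distance threshold (0.5).
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(libraries, outdir, min_len = 400L,
                            strict_len = TRUE, anchors = anchor_config(),
                            top_clusters = 100L, top_codon = 10L,
                            cluster_threshold = 0.5, seed = 1L) {
  if (length(libraries) < 1L || is.null(names(libraries))) {
    stop("at least one named library is required")
  }
  for (lib in names(libraries)) {
    L <- libraries[[lib]]
    if (is.null(L$organism) || !L$organism %in% c("bacteria", "yeast")) {
      stop("library '", lib, "': organism must be 'bacteria' or 'yeast'")
    }
    if (length(L$rounds) < 1L) {
      stop("library '", lib, "': needs round files (round 0 first)")
    }
  }
  if (is.list(anchors) && !inherits(anchors, "anchor_config")) {
    anchors <- do.call(anchor_config, anchors)
  }
  structure(list(libraries = libraries, outdir = outdir,
                 min_len = min_len, strict_len = strict_len,
                 anchors = anchors, top_clusters = top_clusters,
                 top_codon = top_codon,
                 cluster_threshold = cluster_threshold, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file mirroring the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  libs <- lapply(j$libraries, function(L) {
    list(organism = L$organism, rounds = unlist(L$rounds))
  })
  args <- j[setdiff(names(j), "libraries")]
  if (!is.null(args$anchors)) args$anchors <- do.call(anchor_config,
                                                      args$anchors)
  do.call(pipeline_config, c(list(libraries = libs), args))
}

stage_log <- function(...) message("[vnarpan] ", ...)

#' Run the full biopanning analysis pipeline
#'
#' Per library x round: length filtering, CDR3 annotation with
#' rejection accounting, a clonotype round table (TSV) and length
#' statistics. Per library: enrichment trajectories of the final-round
#' top 10, a neighbor-joining tree and single-linkage clusters of the
#' final-round top `top_clusters`, and a rare-codon report of the naive
#' and final rounds. Per library pair: shared-clonotype abundance
#' correlations for round 0 and the final round. A JSON manifest
#' records the configuration and every output path.
#'
#' @param cfg A [pipeline_config()] (or path to its JSON form).
#' @return The manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  for (lib in names(cfg$libraries)) {
    missing <- !file.exists(cfg$libraries[[lib]]$rounds)
    if (any(missing)) {
      stop("missing input for (", lib, ", round ",
           which(missing)[1] - 1L, "): ",
           cfg$libraries[[lib]]$rounds[which(missing)[1]])
    }
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "vnarpan",
                   version = as.character(utils::packageVersion("vnarpan")),
                   seed = cfg$seed,
                   config = list(min_len = cfg$min_len,
                                 strict_len = cfg$strict_len,
                                 anchors = unclass(cfg$anchors),
                                 top_clusters = cfg$top_clusters,
                                 top_codon = cfg$top_codon,
                                 cluster_threshold = cfg$cluster_threshold,
                                 libraries = cfg$libraries),
                   outputs = list(), stats = list())
  tables <- list()
  for (lib in names(cfg$libraries)) {
    L <- cfg$libraries[[lib]]
    tables[[lib]] <- list()
    for (rd in seq_along(L$rounds) - 1L) {
      label <- paste0(lib, "/R", rd)
      stage_log("reading ", label, ": ", L$rounds[rd + 1L])
      reads <- read_sequences(L$rounds[rd + 1L])
      kept <- filter_by_length(reads, cfg$min_len, cfg$strict_len)
      ann <- annotate_all(kept, cfg$anchors)
      stage_log(label, ": ", nrow(reads), " reads, ",
                attr(kept, "tally")[["kept"]], " passed length, ",
                nrow(ann$records), " CDR3 extracted (",
                paste(names(ann$rejections), ann$rejections,
                      sep = "=", collapse = ", "), ")")
      if (nrow(ann$records) == 0L) {
        stop("stage tally failed for ", label, ": no CDR3 records")
      }
      tab <- tally(ann$records, label)
      f <- file.path(cfg$outdir, sprintf("%s_R%d_table.tsv", lib, rd))
      write_round_table(tab, f)
      ls <- length_stats(tab)
      manifest$outputs[[paste0(lib, "_R", rd, "_table")]] <- f
      manifest$stats[[label]] <-
        list(reads = nrow(reads),
             passed_length = unname(attr(kept, "tally")[["kept"]]),
             cdr3_reads = tab$total, unique_cdr3 = length(tab$counts),
             rejections = as.list(ann$rejections),
             median_len = ls$median, max_len = ls$max)
      tables[[lib]][[rd + 1L]] <- tab
    }
  }
  for (lib in names(tables)) {
    tabs <- tables[[lib]]
    final <- tabs[[length(tabs)]]
    top10 <- top_n(final, 10L)$cdr3
    traj <- do.call(rbind, lapply(top10, function(s) {
      tr <- trajectory(tabs, s)
      cbind(cdr3 = s, tr)
    }))
    f <- file.path(cfg$outdir, paste0(lib, "_trajectories.tsv"))
    utils::write.table(traj, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$outputs[[paste0(lib, "_trajectories")]] <- f
    topc <- top_n(final, cfg$top_clusters)$cdr3
    if (length(topc) >= 2L) {
      d <- pairwise_distances(topc)
      f <- file.path(cfg$outdir, paste0(lib, "_top_distances.tsv"))
      utils::write.table(d, f, sep = "\t", quote = FALSE,
                         row.names = TRUE, col.names = NA)
      manifest$outputs[[paste0(lib, "_distances")]] <- f
      f <- file.path(cfg$outdir, paste0(lib, "_top_tree.nwk"))
      write_newick(nj_tree(d), f)
      manifest$outputs[[paste0(lib, "_tree")]] <- f
      cl <- assign_clusters(d, cfg$cluster_threshold)
      f <- file.path(cfg$outdir, paste0(lib, "_clusters.tsv"))
      utils::write.table(data.frame(cdr3 = names(cl), cluster = cl),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$outputs[[paste0(lib, "_clusters")]] <- f
    }
    usage <- load_codon_usage(cfg$libraries[[lib]]$organism)
    for (which_rd in unique(c(1L, length(tabs)))) {
      st <- cohort_rare_codon_stats(tabs[[which_rd]], usage,
                                    cfg$top_codon)
      tag <- paste0(lib, "_R", which_rd - 1L, "_codon")
      f <- file.path(cfg$outdir, paste0(tag, ".tsv"))
      utils::write.table(st$per_clonotype, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$outputs[[tag]] <- f
      manifest$stats[[tag]] <- list(mean = st$mean, sd = st$sd, n = st$n)
    }
  }
  libs <- names(tables)
  if (length(libs) >= 2L) {
    for (i in seq_len(length(libs) - 1L)) {
      for (j in seq.int(i + 1L, length(libs))) {
        a <- tables[[libs[i]]]
        b <- tables[[libs[j]]]
        for (rd in unique(c(1L, min(length(a), length(b))))) {
          cmp <- tryCatch(shared_abundance_correlation(a[[rd]], b[[rd]]),
                          error = function(e) NULL)
          tag <- paste0(libs[i], "_vs_", libs[j], "_R", rd - 1L)
          manifest$stats[[tag]] <-
            if (is.null(cmp)) list(r = NA, n_shared = 0)
            else list(r = cmp$r, n_shared = cmp$n_shared)
        }
      }
    }
  }
  f <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  stage_log("manifest written to ", f)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `inst/cli/vnarpan` script:
#' `run --config cfg.json`, `simulate --mode phage|yeast|paired --seed S
#' --out DIR`, `filter`, `extract`, `tally`, `compare`, `cluster`,
#' `codon`. Flags override JSON config values.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
vnarpan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: vnarpan <command> [options]",
    "  run      --config cfg.json",
    "  simulate --mode phage|yeast|paired [--seed S] [--out DIR]",
    "  filter   --in reads.fastq --out kept.fastq [--min-len 400]",
    "           [--inclusive]",
    "  extract  --in reads.fastq --out records.tsv [--anchor5 RE]",
    "           [--anchor3 RE] [--min-cdr3 N] [--max-cdr3 N]",
    "  tally    --in records.tsv --out table.tsv [--label L]",
    "  compare  --a table.tsv --b table.tsv",
    "  cluster  --in table.tsv --top N --threshold T --out tree.nwk",
    "  codon    --in table.tsv --organism bacteria|yeast --top N",
    sep = "\n")
  if (length(args) == 0L) {
    cat(usage, "\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_flags(args[-1])
  get <- function(k, default = NULL) {
    if (!is.null(opt[[k]])) opt[[k]] else default
  }
  status <- 0L
  tryCatch(switch(cmd,
    run = {
      run_pipeline(get("config", stop("run: --config required")))
    },
    simulate = {
      cfg <- sim_config(seed = as.integer(get("seed", 1)))
      mode <- get("mode", "paired")
      out <- get("out", "vnarpan_sim")
      if (mode == "paired") {
        pr <- simulate_paired(cfg)
        write_campaign(pr$phage, out)
        write_campaign(pr$yeast, out)
      } else {
        write_campaign(simulate_campaign(cfg, mode), out)
      }
      stage_log("simulation written to ", out)
    },
    filter = {
      reads <- read_sequences(get("in", stop("filter: --in required")))
      kept <- filter_by_length(reads,
                               as.integer(get("min-len", 400)),
                               strict = is.null(opt[["inclusive"]]))
      write_sequences(kept, get("out", stop("filter: --out required")))
    },
    extract = {
      anchors <- anchor_config(
        five_prime = get("anchor5", "[YF][YF]C"),
        three_prime = get("anchor3", "[DN]G[AG]GT"),
        min_cdr3_len = as.integer(get("min-cdr3", 3)),
        max_cdr3_len = as.integer(get("max-cdr3", 35)))
      reads <- read_sequences(get("in", stop("extract: --in required")))
      res <- annotate_all(reads, anchors)
      utils::write.table(res$records,
                         get("out", stop("extract: --out required")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stage_log(paste(names(res$rejections), res$rejections,
                      sep = "=", collapse = ", "))
    },
    tally = {
      rec <- utils::read.table(get("in", stop("tally: --in required")),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      write_round_table(tally(rec, get("label", "library/R0")),
                        get("out", stop("tally: --out required")))
    },
    compare = {
      cmp <- shared_abundance_correlation(
        read_round_table(get("a", stop("compare: --a required"))),
        read_round_table(get("b", stop("compare: --b required"))))
      cat(jsonlite::toJSON(list(r = cmp$r, n_shared = cmp$n_shared),
                           auto_unbox = TRUE), "\n")
    },
    cluster = {
      tab <- read_round_table(get("in", stop("cluster: --in required")))
      seqs <- top_n(tab, as.integer(get("top", 100)))$cdr3
      d <- pairwise_distances(seqs)
      write_newick(nj_tree(d), get("out", "tree.nwk"))
      cl <- assign_clusters(d, as.numeric(get("threshold", 0.5)))
      utils::write.table(data.frame(cdr3 = names(cl), cluster = cl),
                         stdout(), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    codon = {
      tab <- read_round_table(get("in", stop("codon: --in required")))
      st <- cohort_rare_codon_stats(
        tab, load_codon_usage(get("organism", "bacteria")),
        as.integer(get("top", 10)))
      cat(jsonlite::toJSON(list(mean = st$mean, sd = st$sd, n = st$n),
                           auto_unbox = TRUE), "\n")
    },
    {
      cat(usage, "\n")
      status <- 1L
    }
  ), error = function(e) {
    message("vnarpan ", cmd, ": ", conditionMessage(e))
    status <<- 1L
  })
  invisible(status)
}

# --flag value / bare --flag parsing
parse_flags <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opt[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opt[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  opt
}
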