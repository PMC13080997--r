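#' Run configuration for a multi-state comparison
#'
#' A single YAML file declares the catalytic states (each a topology plus
#' trajectory files), named regions, the ordered state transitions to
#' difference, and per-analysis parameters; [run_pipeline()] executes it and
#' writes plain-text artifacts plus a manifest from which the run is fully
#' reconstructable.
#'
#' @section Schema:
#' \preformatted{
#' output_dir: out/
#' seed: 1
#' states:
#'   - label: ATP
#'     topology: atp.pdb
#'     trajectories: [atp_r1.pdb, atp_r2.pdb]
#' transitions:        # [from, to]; delta file is DF(to) - DF(from)
#'   - [apo, ATP]
#' regions:
#'   L5: "116-134"
#' profiles:           # per-residue rows of a transition's delta matrix
#'   - {transition: [ATP, ADP], residue: 127}
#' analyses:
#'   df:  {enabled: true, mode: pooled}
#'   spm: {enabled: true, cutoff: 6.0, keep_frac: 0.2}
#'   clustering: {enabled: false, loop: "111-140",
#'                anchor: "111-116,135-140", epsilon: 5.0, atoms: backbone}
#' }
#'
#' @param path YAML file.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, dir = dirname(path))
}

validate_run_config <- function(cfg, dir = ".") {
  if (is.null(cfg$states) || !length(cfg$states)) {
    stop("config must declare at least one state")
  }
  labels <- vapply(cfg$states, function(s) s$label %||% "", character(1))
  if (any(labels == "")) stop("every state needs a 'label'")
  if (anyDuplicated(labels)) stop("duplicate state labels")
  for (s in cfg$states) {
    if (is.null(s$topology)) stop("state '", s$label, "' lacks a topology")
    if (is.null(s$trajectories) || !length(s$trajectories)) {
      stop("state '", s$label, "' lacks trajectories")
    }
  }
  for (tr in cfg$transitions %||% list()) {
    if (length(tr) != 2L || !all(unlist(tr) %in% labels)) {
      stop("transition [", paste(unlist(tr), collapse = ", "),
           "] must reference two declared state labels")
    }
  }
  for (p in cfg$profiles %||% list()) {
    if (length(p$transition %||% NULL) != 2L ||
        !all(unlist(p$transition) %in% labels) || is.null(p$residue)) {
      stop("each profile needs transition: [from, to] and residue")
    }
  }
  an <- cfg$analyses %||% list()
  an$df <- utils::modifyList(list(enabled = TRUE, mode = "pooled"),
                             an$df %||% list())
  an$spm <- utils::modifyList(list(enabled = TRUE, cutoff = 6.0,
                                   keep_frac = 0.2, ref_epsilon = 2.0),
                              an$spm %||% list())
  an$clustering <- utils::modifyList(
    list(enabled = FALSE, loop = "111-140", anchor = "111-116,135-140",
         epsilon = 5.0, atoms = "backbone", linkage = "average"),
    an$clustering %||% list())
  if (an$spm$cutoff <= 0 || an$clustering$epsilon <= 0) {
    stop("cutoff and epsilon must be positive")
  }
  cfg$analyses <- an
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "allokin_out"
  cfg$.dir <- dir
  class(cfg) <- "run_config"
  cfg
}

resolve_path <- function(p, dir) {
  if (file.exists(p)) p else file.path(dir, p)
}

#' Execute a full multi-state analysis
#'
#' For every state: a distance-fluctuation matrix and, when enabled, the
#' shortest-path-map artifacts (correlation and mean-distance matrices, edge
#' and node tables, drawing script) and the loop-clustering outputs (frame
#' labels, cluster populations, centroid PDB files). For every transition: a
#' delta matrix (end state minus start state) and any requested per-residue
#' profiles. A `manifest.yaml` records parameters, seeds and input checksums;
#' re-running the same configuration reproduces the numeric artifacts
#' byte-identically.
#'
#' @param config a `run_config` or path to a YAML file.
#' @param output_dir overrides the configured output directory.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- output_dir %||% config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  an <- config$analyses
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  checksums <- list()
  dfs <- list()
  for (s in config$states) {
    lab <- s$label
    top_path <- resolve_path(s$topology, config$.dir)
    traj_paths <- vapply(s$trajectories, resolve_path, character(1),
                         dir = config$.dir)
    checksums[[lab]] <- as.list(tools::md5sum(c(top_path, traj_paths)))
    top <- stage(paste0("load:", lab), load_structure(top_path))
    traj <- stage(paste0("load:", lab), load_trajectory(top, traj_paths))

    if (isTRUE(an$df$enabled)) {
      dfs[[lab]] <- stage(paste0("df:", lab),
        compute_df(traj, replica_mode = an$df$mode, state = lab))
      write_score_matrix(dfs[[lab]], file.path(out, paste0("df_", lab,
                                                           ".mat")))
    }
    if (isTRUE(an$spm$enabled)) {
      stage(paste0("spm:", lab), {
        ref <- reference_structure(traj, epsilon = an$spm$ref_epsilon)
        cm <- correlation_matrix(traj, reference = ref$frame)
        dm <- average_distance_matrix(traj)
        write_score_matrix(cm, file.path(out, paste0("cor_", lab, ".mat")))
        write_score_matrix(dm, file.path(out, paste0("avgdist_", lab,
                                                     ".mat")))
        kg <- build_graph(cm, dm, cutoff = an$spm$cutoff)
        spm <- shortest_path_map(kg, keep_frac = an$spm$keep_frac)
        export_spm(spm, top, file.path(out, paste0("spm_", lab, "_")))
      })
    }
    if (isTRUE(an$clustering$enabled)) {
      stage(paste0("clustering:", lab), {
        cc <- cluster_config(loop = an$clustering$loop,
                             anchor = an$clustering$anchor,
                             atoms = an$clustering$atoms,
                             epsilon = an$clustering$epsilon,
                             linkage = an$clustering$linkage)
        red <- protocol_transform(traj, cc)
        cl <- hier_cluster(red, epsilon = cc$epsilon, linkage = cc$linkage)
        utils::write.table(
          data.frame(frame = seq_along(cl$labels), cluster = cl$labels),
          file.path(out, paste0("clusters_", lab, "_labels.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          data.frame(cluster = seq_len(cl$n_clusters),
                     population = cl$populations,
                     centroid_frame = cl$centroid_frames),
          file.path(out, paste0("clusters_", lab, "_populations.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        for (k in seq_len(cl$n_clusters)) {
          write_structure(red$top,
                          file.path(out, sprintf("clusters_%s_centroid%d.pdb",
                                                 lab, k)),
                          xyz = get_frame(red, cl$centroid_frames[k]))
        }
      })
    }
  }

  for (tr in config$transitions %||% list()) {
    from <- tr[[1]]; to <- tr[[2]]
    if (is.null(dfs[[from]]) || is.null(dfs[[to]])) {
      stop("transition [", from, ", ", to,
           "] requires the df analysis to be enabled")
    }
    dd <- stage(paste0("ddf:", from, "->", to),
                delta_df(dfs[[to]], dfs[[from]]))
    write_score_matrix(dd, file.path(out, paste0(
      "ddf_", to, "-minus-", from, ".mat")))
  }
  for (p in config$profiles %||% list()) {
    from <- p$transition[[1]]; to <- p$transition[[2]]
    dd <- delta_df(dfs[[to]], dfs[[from]])
    prof <- residue_profile(dd, p$residue)
    utils::write.table(
      data.frame(resno = as.integer(names(prof)),
                 delta = format(prof, digits = 17, trim = TRUE)),
      file.path(out, sprintf("profile_%s-minus-%s_res%d.tsv",
                             to, from, p$residue)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "allokin",
    version = as.character(utils::packageVersion("allokin")),
    seed = config$seed,
    analyses = config$analyses,
    states = lapply(config$states, function(s) {
      list(label = s$label, topology = s$topology,
           trajectories = s$trajectories)
    }),
    transitions = config$transitions %||% list(),
    regions = config$regions %||% list(),
    input_md5 = checksums)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(out)
}
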