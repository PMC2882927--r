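# Orchestration: one config drives simulation (or file inputs) through
# genetics, clustering, assignment, mtDNA, niche and connectivity stages,
# writing per-stage CSV/JSON artifacts and a summary.

stage_seed <- function(config, stage) {
  # deterministic per-stage seed: global seed + a stable hash of the name
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 9973L
  (config$seed %% 100000L) * 10000L + h
}

#' Default run configuration
#'
#' Flat list of per-stage parameter blocks; every stochastic stage
#' derives its seed deterministically from the global \code{seed} and its
#' stage name.  Defaults are desk-scale: MCMC 2000+2000 sweeps (far below
#' the field-standard 50000 — raise for production data), 3 replicate
#' runs over K = 1..4.
#'
#' @param seed global seed.
#' @param output_dir artifact directory.
#' @param ... overrides for any block (scenario, clustering, assignment,
#'   richness, ibd, mtdna, niche, connectivity).
#' @return config list.
#' @export
default_config <- function(seed = 1, output_dir = tempfile("phylogap_run"),
                           ...) {
  cfg <- list(
    seed = as.integer(seed),
    output_dir = output_dir,
    scenario = list(),
    clustering = list(k_range = 1:4, n_runs = 3, burnin = 2000,
                      reps = 2000),
    assignment = list(n_sim = 1000, alpha = 0.01),
    richness = list(n_perm = 1000),
    ibd = list(transform = "linear", n_perm = 1000),
    mtdna = list(rate_per_lineage = 0.007, confidence = 0.95),
    niche = list(beta = 1.0, thresholds = default_thresholds(),
                 area_threshold = 0.1, cell_area_km2 = 100),
    connectivity = list(neighborhood = 8)
  )
  utils::modifyList(cfg, list(...))
}

#' Read a YAML run configuration
#' @param path YAML file with the blocks of \code{\link{default_config}}.
#' @return config list (defaults filled in).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  utils::modifyList(cfg, user)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or load) data; pairwise F_ST/R_ST and Nm;
#' rarefied richness + permutation test; isolation by distance;
#' admixture clustering with delta-K; assignment and migrant detection;
#' mtDNA distances, clock dating, diversity, haplotype network; niche
#' models for both lineages with evaluation and areas; gap connectivity.
#' Artifacts (CSV/JSON) are written under \code{config$output_dir}; a
#' rerun with the same config writes byte-identical artifacts.
#'
#' @param config list from \code{\link{default_config}} or
#'   \code{\link{read_config}}.
#' @return invisibly, the report list (also written as
#'   \code{summary.json}).
#' @export
run_full_analysis <- function(config = default_config()) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)

  run_stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- data ---------------------------------------------------------------
  sc <- do.call(scenario, c(config$scenario,
                            list(seed = stage_seed(config, "simulate"))))
  ms <- run_stage("simulate", simulate_microsatellites(sc))
  aln <- run_stage("simulate", simulate_mtdna(sc))
  land <- run_stage("simulate", simulate_landscape(sc))
  g <- ms$genotypes
  loc <- ms$localities
  cluster_of <- setNames(loc$cluster, loc$locality_id)
  grouping <- unname(cluster_of[g$locality_ids])

  # --- classical genetics -------------------------------------------------
  report$genetics <- run_stage("genetics", {
    fst <- fst_pairwise(g, grouping)
    rst <- rst_pairwise(g, grouping)
    write_pairwise_csv(fst, file.path(out, "fst.csv"))
    write_pairwise_csv(rst, file.path(out, "rst.csv"))
    nm <- rst$values
    nm[] <- NA
    off <- upper.tri(nm) | lower.tri(nm)
    pos <- off & rst$values > 0
    nm[pos] <- nm_from_fixation(rst$values[pos])
    write.csv(as.data.frame(nm), file.path(out, "nm.csv"))
    list(mean_fst = mean(fst$values[upper.tri(fst$values)], na.rm = TRUE),
         mean_rst = mean(rst$values[upper.tri(rst$values)], na.rm = TRUE))
  })

  # --- richness -----------------------------------------------------------
  report$richness <- run_stage("richness", {
    rt <- allelic_richness(g)
    pt <- richness_permutation_test(
      rt, setNames(unname(cluster_of[rownames(rt$richness)]),
                   rownames(rt$richness)),
      n_perm = config$richness$n_perm,
      seed = stage_seed(config, "richness"))
    write.csv(cbind(as.data.frame(rt$richness), mean = rt$mean),
              file.path(out, "richness.csv"))
    list(g = rt$g, p_value = pt$p_value)
  })

  # --- isolation by distance ----------------------------------------------
  report$ibd <- run_stage("ibd", {
    rst_loc <- rst_pairwise(g)
    locs <- loc[match(rst_loc$labels, loc$locality_id), ]
    km <- geographic_distance_km(locs)
    mt <- mantel_test(rst_loc, km, transform = config$ibd$transform,
                      n_perm = config$ibd$n_perm,
                      seed = stage_seed(config, "ibd"))
    mt[c("r", "r_squared", "p_value")]
  })

  # --- clustering ---------------------------------------------------------
  report$clustering <- run_stage("clustering", {
    cl <- config$clustering
    runs <- admixture_scan(g, k_range = cl$k_range, n_runs = cl$n_runs,
                           burnin = cl$burnin, reps = cl$reps,
                           seed = stage_seed(config, "clustering"))
    dk <- delta_k(runs)
    write.csv(dk, file.path(out, "delta_k.csv"), row.names = FALSE)
    best_k <- attr(dk, "best_k")
    fits <- attr(runs, "fits")
    lab <- vapply(fits, function(f) f$K == best_k, TRUE)
    best_fit <- fits[lab][[which.max(vapply(fits[lab], `[[`, 0, "lnpd"))]]
    write.csv(as.data.frame(best_fit$Q), file.path(out, "q_matrix.csv"))
    memb <- membership_by_locality(best_fit, g$locality_ids)
    write.csv(as.data.frame(memb), file.path(out, "membership.csv"))
    list(best_k = best_k,
         mean_max_q = mean(apply(best_fit$Q, 1, max)))
  })

  # --- assignment / migrants ----------------------------------------------
  report$assignment <- run_stage("assignment", {
    sc_as <- assignment_scores(g, method = "frequency")
    write.csv(sc_as[sc_as$rank <= 5, ],
              file.path(out, "assignment.csv"), row.names = FALSE)
    mig <- detect_first_gen_migrants(
      g, n_sim = config$assignment$n_sim,
      alpha = config$assignment$alpha,
      seed = stage_seed(config, "assignment"))
    write.csv(mig, file.path(out, "migrants.csv"), row.names = FALSE)
    list(self_assignment = self_assignment_rate(sc_as),
         n_flagged = sum(mig$flagged))
  })

  # --- mtDNA --------------------------------------------------------------
  report$mtdna <- run_stage("mtdna", {
    grp <- sub("_[0-9]+$", "", aln$ids)
    pd <- p_distance(aln)
    tn <- tn93_distance(aln)
    write_pairwise_csv(pd, file.path(out, "p_dist.csv"))
    write_pairwise_csv(tn, file.path(out, "tn93.csv"))
    gm <- group_mean_distance(pd, grp)
    times <- divergence_time(gm$between,
                             config$mtdna$rate_per_lineage)
    write.csv(as.data.frame(times), file.path(out, "divergence_myr.csv"))
    div <- lapply(split(seq_along(grp), grp), function(ix) {
      if (length(ix) < 2) return(NULL)
      d <- diversity_indices(seq_alignment(aln$ids[ix],
                                           aln$sequences[ix]))
      data.frame(n = d$n, h = d$h, s = d$s, hd = d$hd, pi = d$pi)
    })
    div <- do.call(rbind, div)
    write.csv(div, file.path(out, "diversity.csv"))
    ht <- haplotype_table(aln, grp)
    lim <- parsimony_connection_limit(aln$length,
                                      config$mtdna$confidence)
    net <- build_haplotype_network(ht, lim)
    el <- igraph::as_data_frame(net, what = "edges")
    write.csv(el, file.path(out, "network_edges.csv"), row.names = FALSE)
    list(n_haplotypes = length(ht$haplotype), connection_limit = lim,
         n_network_components = igraph::components(net)$no,
         basal_divergence_myr = times["North", grep("South_1",
                                                    colnames(times))[1]])
  })

  # --- niche models -------------------------------------------------------
  report$niche <- run_stage("niche", {
    ncfg <- config$niche
    fit_one <- function(presences, vars) {
      stk <- climate_stack(land$current[vars])
      m <- fit_maxent(presences, stk, beta = ncfg$beta)
      cur <- predict_logistic(m, land$current)
      lgm <- predict_logistic(m, land$lgm)
      auc <- auc_presence_background(cur, presences,
                                     stack_cells(land$current))
      list(model = m, current = cur, lgm = lgm, auc = auc)
    }
    # each lineage modeled on its limiting variables: the northern
    # envelope is altitude-driven, the southern is precipitation-driven
    north <- fit_one(land$presences_north, "alt")
    south <- fit_one(land$presences_south, c("precip", "temp"))
    write_ascii_grid(north$current, file.path(out, "suit_north_current.asc"))
    write_ascii_grid(north$lgm, file.path(out, "suit_north_lgm.asc"))
    write_ascii_grid(south$current, file.path(out, "suit_south_current.asc"))
    write_ascii_grid(south$lgm, file.path(out, "suit_south_lgm.asc"))
    east <- seq(max(land$gap_cols) + 1L, ncol(south$current$values))
    east_mask <- matrix(FALSE, nrow(south$current$values),
                        ncol(south$current$values))
    east_mask[, east] <- TRUE
    res <- list(
      auc_north = north$auc, auc_south = south$auc,
      area_south_current = suitable_area(south$current,
                                         ncfg$area_threshold,
                                         ncfg$cell_area_km2, east_mask),
      area_south_lgm = suitable_area(south$lgm, ncfg$area_threshold,
                                     ncfg$cell_area_km2, east_mask))
    attr(res, "rasters") <- list(north = north, south = south)
    res
  })

  # --- connectivity -------------------------------------------------------
  report$connectivity <- run_stage("connectivity", {
    rasters <- attr(report$niche, "rasters")
    nr <- nrow(land$gap_mask)
    west_border <- data.frame(row = seq_len(nr),
                              col = min(land$gap_cols) - 1L)
    east_border <- data.frame(row = seq_len(nr),
                              col = max(land$gap_cols) + 1L)
    rep_for <- function(side) {
      gap_connectivity_report(side$current, side$lgm, land$gap_mask,
                              west_border, east_border,
                              config$connectivity$neighborhood)
    }
    s <- rep_for(rasters$south); n <- rep_for(rasters$north)
    list(south = s[c("cost_current", "cost_lgm", "verdict")],
         north = n[c("cost_current", "cost_lgm", "verdict")])
  })

  attr(report$niche, "rasters") <- NULL
  write_json_artifact(report, file.path(out, "summary.json"))
  invisible(report)
}
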