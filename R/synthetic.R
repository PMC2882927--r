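# Seeded synthetic-data generator: hierarchical microsatellite structure
# with isolation by distance, clock-like mtDNA on a cluster tree, and a
# two-gradient climate landscape with an unsuitable gap band.

#' Run code with a local, restorable RNG state
#'
#' All generator randomness flows through this helper so that a scenario's
#' seed fully determines its output and never leaks into (or depends on)
#' the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Define a simulation scenario
#'
#' The defaults emulate the sampling design of the study system the
#' package targets: 4 genetic clusters (one northern lineage, three
#' southern), 25 localities, 19 diploid individuals per locality typed at
#' 6 microsatellite loci; a 487-bp mtDNA fragment evolving at 0.007
#' substitutions/site/Myr per lineage on a cluster tree with a ~5-Myr
#' basal (north/south) split; and a gridded two-gradient climate
#' landscape in which a band of intermediate-precipitation cells forms a
#' gap that is unsuitable for the moist-adapted southern lineage.
#'
#' @param n_clusters number of genetic clusters (first = northern lineage).
#' @param localities_per_cluster integer vector (recycled) of localities.
#' @param individuals_per_locality diploid individuals per locality.
#' @param n_loci microsatellite loci.
#' @param step_rate stepwise-mutation steps per Myr along the cluster tree
#'   (controls between-cluster allele-size divergence).
#' @param allele_geom within-deme allele-size dispersal: P(size = mode + k)
#'   proportional to \code{allele_geom^|k|}.
#' @param ibd_sd per-locality-step s.d. of the allele-size drift walk along
#'   each cluster's transect (controls isolation by distance).
#' @param admix_weights optional vector of length \code{n_clusters}: adds
#'   one admixed locality whose allele copies draw their cluster of origin
#'   with these weights.
#' @param mtdna_length sites in the mtDNA alignment.
#' @param subst_rate per-lineage substitution rate (subs/site/Myr).
#' @param split_times named list: \code{basal} (north vs south),
#'   \code{south_deep} (South_3 vs South_1+2), \code{south_shallow}
#'   (South_1 vs South_2), in Myr.
#' @param tip_depth per-cluster within-cluster coalescent depth (Myr),
#'   recycled over clusters.
#' @param mtdna_per_cluster sequences sampled per cluster (recycled).
#' @param landscape list: \code{nrows}, \code{ncols}, \code{gap_cols}
#'   (column range of the gap band), \code{lgm_precip_shift} (mm),
#'   \code{n_presence} per lineage.
#' @param seed integer RNG seed; fixed seed implies byte-identical output.
#' @return object of class \code{scenario} (a validated list).
#' @export
scenario <- function(n_clusters = 4,
                     localities_per_cluster = c(8, 6, 6, 5),
                     individuals_per_locality = 19,
                     n_loci = 6,
                     step_rate = 3,
                     allele_geom = 0.5,
                     ibd_sd = 0.6,
                     admix_weights = NULL,
                     mtdna_length = 487,
                     subst_rate = 0.007,
                     split_times = list(basal = 5.0, south_deep = 3.6,
                                        south_shallow = 1.4),
                     tip_depth = c(0.0, 0.3, 0.8, 1.9),
                     mtdna_per_cluster = c(10, 9, 9, 7),
                     landscape = list(nrows = 40, ncols = 60,
                                      gap_cols = 26:35,
                                      lgm_precip_shift = 600,
                                      n_presence = 40),
                     seed = 1) {
  sc <- list(n_clusters = as.integer(n_clusters),
             localities_per_cluster =
               rep_len(as.integer(localities_per_cluster), n_clusters),
             individuals_per_locality = as.integer(individuals_per_locality),
             n_loci = as.integer(n_loci),
             step_rate = step_rate, allele_geom = allele_geom,
             ibd_sd = ibd_sd, admix_weights = admix_weights,
             mtdna_length = as.integer(mtdna_length),
             subst_rate = subst_rate, split_times = split_times,
             tip_depth = rep_len(tip_depth, n_clusters),
             mtdna_per_cluster = rep_len(as.integer(mtdna_per_cluster),
                                         n_clusters),
             landscape = landscape,
             seed = as.integer(seed))
  stopifnot(sc$n_clusters >= 1, all(sc$localities_per_cluster >= 1),
            sc$individuals_per_locality >= 1, sc$n_loci >= 1,
            sc$mtdna_length >= 1, sc$subst_rate > 0,
            all(unlist(sc$split_times) >= 0),
            sc$allele_geom >= 0, sc$allele_geom < 1)
  if (!is.null(admix_weights) && length(admix_weights) != n_clusters)
    stop("admix_weights must have length n_clusters")
  class(sc) <- "scenario"
  sc
}

cluster_names <- function(sc) {
  if (sc$n_clusters == 1L) return("C1")
  c("North", paste0("South_", seq_len(sc$n_clusters - 1L)))
}

# height of the split separating clusters i and j on the default topology
# (North, (South_1, South_2), South_3): used for both markers
cluster_split_myr <- function(sc, i, j) {
  if (i == j) return(0)
  st <- sc$split_times
  if (i == 1L || j == 1L) return(st$basal)
  a <- max(i, j)
  if (a == 4L) return(st$south_deep)
  st$south_shallow
}

#' Locality table for a scenario
#'
#' Localities are laid out on a west-to-east transect (clusters in order,
#' with a longitude gap after the first cluster, mirroring a distribution
#' gap), which makes within-cluster geographic distance proportional to
#' transect position.
#'
#' @param sc a \code{\link{scenario}}.
#' @return data.frame: locality_id, latitude, longitude, cluster.
#' @export
scenario_localities <- function(sc) {
  rows <- list()
  lon <- -85.5
  for (c in seq_len(sc$n_clusters)) {
    cl <- cluster_names(sc)[c]
    for (l in seq_len(sc$localities_per_cluster[c])) {
      rows[[length(rows) + 1L]] <-
        data.frame(locality_id = sprintf("%s_L%02d", cl, l),
                   latitude = 9.5 - 0.02 * length(rows),
                   longitude = lon, cluster = cl,
                   stringsAsFactors = FALSE)
      lon <- lon + 0.25
    }
    if (c == 1L) lon <- lon + 1.8        # the distribution gap
  }
  if (!is.null(sc$admix_weights))
    rows[[length(rows) + 1L]] <-
      data.frame(locality_id = "Admix_L01", latitude = 9.5 - 0.02 *
                   length(rows), longitude = lon + 0.25, cluster = "Admix",
                 stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# two-sided geometric offset sampler around 0
rgeom2 <- function(n, rho) {
  if (rho == 0) return(integer(n))
  mag <- stats::rgeom(n, 1 - rho)
  sgn <- sample(c(-1L, 1L), n, replace = TRUE)
  mag * sgn
}

#' Simulate diploid microsatellite genotypes
#'
#' Cluster modal allele sizes perform a stepwise (+/-1 repeat) random walk
#' along the cluster tree (Poisson number of steps = \code{step_rate} x
#' branch Myr), so deeper splits accumulate larger allele-size
#' displacement and both identity-based (F_ST) and size-based (R_ST)
#' signals exist.  Within a cluster, locality modes drift along the
#' transect (a Gaussian walk of s.d. \code{ibd_sd} per locality), creating
#' isolation by distance; allele copies are drawn around the locality mode
#' with a two-sided geometric kernel.
#'
#' @param sc a \code{\link{scenario}}.
#' @return list: \code{genotypes} (a \code{\link{genotype_matrix}}),
#'   \code{true_q} (individuals x clusters generating membership),
#'   \code{localities} (the locality table).
#' @export
simulate_microsatellites <- function(sc) {
  loc <- scenario_localities(sc)
  with_seed(sc$seed + 101L, {
    K <- sc$n_clusters
    # per-locus ancestral size and per-cluster modal size via tree walk
    anc <- sample(80:140, sc$n_loci, replace = TRUE)
    walk <- function(t) {
      n <- rpois(1, sc$step_rate * t)
      if (n == 0) 0L else sum(sample(c(-1L, 1L), n, replace = TRUE))
    }
    cl_mode <- matrix(0L, K, sc$n_loci)
    st <- sc$split_times
    for (l in seq_len(sc$n_loci)) {
      if (K == 1L) { cl_mode[1, l] <- anc[l]; next }
      north <- anc[l] + walk(st$basal)
      south_anc <- anc[l] + walk(st$basal)
      modes <- north
      if (K >= 2L) {
        s12_anc <- south_anc + walk(max(st$south_deep - st$south_shallow, 0))
        s1 <- s12_anc + walk(st$south_shallow)
        modes <- c(modes, s1)
      }
      if (K >= 3L) {
        s2 <- s12_anc + walk(st$south_shallow)
        modes <- c(modes, s2)
      }
      if (K >= 4L) {
        s3 <- south_anc + walk(st$south_deep)
        modes <- c(modes, s3)
      }
      if (K > 4L) for (e in 5:K)
        modes <- c(modes, south_anc + walk(st$south_deep))
      cl_mode[, l] <- modes
    }
    ids <- locs <- character(0)
    a1 <- a2 <- NULL
    trueq <- NULL
    draw_copy <- function(mode_row) {
      vapply(seq_len(sc$n_loci), function(l)
        as.integer(mode_row[l] + rgeom2(1L, sc$allele_geom)), 0L)
    }
    for (ci in seq_len(K)) {
      nl <- sc$localities_per_cluster[ci]
      drift <- matrix(0, nl, sc$n_loci)
      if (nl > 1L)
        for (l in seq_len(sc$n_loci))
          drift[, l] <- cumsum(c(0, rnorm(nl - 1L, 0, sc$ibd_sd)))
      for (li in seq_len(nl)) {
        lid <- sprintf("%s_L%02d", cluster_names(sc)[ci], li)
        mode_row <- cl_mode[ci, ] + as.integer(round(drift[li, ]))
        for (ii in seq_len(sc$individuals_per_locality)) {
          ids <- c(ids, sprintf("%s_I%02d", lid, ii))
          locs <- c(locs, lid)
          a1 <- rbind(a1, draw_copy(mode_row))
          a2 <- rbind(a2, draw_copy(mode_row))
          q <- numeric(K); q[ci] <- 1
          trueq <- rbind(trueq, q)
        }
      }
    }
    if (!is.null(sc$admix_weights)) {
      w <- sc$admix_weights / sum(sc$admix_weights)
      for (ii in seq_len(sc$individuals_per_locality)) {
        ids <- c(ids, sprintf("Admix_L01_I%02d", ii))
        locs <- c(locs, "Admix_L01")
        copy <- function() vapply(seq_len(sc$n_loci), function(l) {
          ci <- sample.int(K, 1L, prob = w)
          as.integer(cl_mode[ci, l] + rgeom2(1L, sc$allele_geom))
        }, 0L)
        a1 <- rbind(a1, copy()); a2 <- rbind(a2, copy())
        trueq <- rbind(trueq, w)
      }
    }
    colnames(trueq) <- cluster_names(sc)
    rownames(trueq) <- ids
    list(genotypes = genotype_matrix(ids, locs,
                                     paste0("locus", seq_len(sc$n_loci)),
                                     a1, a2),
         true_q = trueq, localities = loc)
  })
}

# Poisson substitutions (Jukes-Cantor style) applied to a sequence vector
mutate_seq <- function(x, n_sub, bases = c("A", "C", "G", "T")) {
  if (n_sub == 0L) return(x)
  sites <- sample.int(length(x), n_sub, replace = TRUE)
  for (s in sites) x[s] <- sample(bases[bases != x[s]], 1L)
  x
}

#' Simulate a clock-like mtDNA alignment
#'
#' A random root sequence evolves along the scenario's cluster tree with
#' Poisson-distributed substitutions (expected number = per-lineage rate x
#' branch Myr x sites; each hit replaces the base with one of the other
#' three).  Within clusters, tips radiate from the cluster ancestor at
#' depth \code{tip_depth}.  For small divergences the expected p-distance
#' between clusters split T Myr ago is about \code{2 * subst_rate * T}.
#'
#' @param sc a \code{\link{scenario}}.
#' @return a \code{\link{seq_alignment}} whose ids are
#'   \code{<cluster>_<k>}.
#' @export
simulate_mtdna <- function(sc) {
  with_seed(sc$seed + 202L, {
    L <- sc$mtdna_length
    r <- sc$subst_rate
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, L, replace = TRUE)
    st <- sc$split_times
    evolve <- function(x, t) mutate_seq(x, rpois(1, r * t * L))
    K <- sc$n_clusters
    td <- sc$tip_depth
    # cluster ancestors sit at depth tip_depth[c] so that tip-to-tip
    # divergence across clusters is exactly 2 x split time
    split_of <- c(st$basal, st$south_shallow, st$south_shallow,
                  rep(st$south_deep, max(K - 3L, 0L)))[seq_len(K)]
    if (any(td[seq_len(K)] > split_of))
      stop("tip_depth must not exceed the cluster's split time")
    anc <- vector("list", K)
    if (K == 1L) anc[[1]] <- root else {
      anc[[1]] <- evolve(root, st$basal - td[1])         # North
      south <- evolve(root, st$basal - st$south_deep)
      s12 <- evolve(south, st$south_deep - st$south_shallow)
      if (K >= 2L) anc[[2]] <- evolve(s12, st$south_shallow - td[2])
      if (K >= 3L) anc[[3]] <- evolve(s12, st$south_shallow - td[3])
      if (K >= 4L) for (e in 4:K) anc[[e]] <-
          evolve(south, st$south_deep - td[e])
    }
    ids <- seqs <- character(0)
    for (ci in seq_len(K)) {
      for (k in seq_len(sc$mtdna_per_cluster[ci])) {
        tip <- evolve(anc[[ci]], sc$tip_depth[ci])
        ids <- c(ids, sprintf("%s_%02d", cluster_names(sc)[ci], k))
        seqs <- c(seqs, paste(tip, collapse = ""))
      }
    }
    seq_alignment(ids, seqs)
  })
}

#' Simulate current and glacial climate landscapes with a gap band
#'
#' Three layers on a grid: a precipitation-like gradient rising west to
#' east (dry northern range, moist southern range) with a dip over the
#' gap band; a temperature-like gradient varying north to south; and an
#' altitude layer falling west to east.  Ground-truth suitability is a
#' known function of one gradient per lineage: the moist-adapted southern
#' lineage follows a logistic envelope of high precipitation, so the
#' intermediate-precipitation gap is poor under current conditions and
#' poorer still under the glacial scenario (precipitation shifted down by
#' \code{lgm_precip_shift}); the northern lineage follows a Gaussian
#' envelope of altitude, which does not change between periods, so the
#' gap's resistance for the northern lineage is period-invariant by
#' construction.
#'
#' @param sc a \code{\link{scenario}}.
#' @return list: \code{current}, \code{lgm} (\code{\link{climate_stack}}s
#'   with layers \code{precip}, \code{temp}, \code{alt}),
#'   \code{presences_north}, \code{presences_south} (data.frames of
#'   row/col cells), \code{truth_north}, \code{truth_south} (ground-truth
#'   suitability rasters, current climate), \code{gap_mask} (logical
#'   matrix), \code{gap_cols}.
#' @export
simulate_landscape <- function(sc) {
  ls <- sc$landscape
  with_seed(sc$seed + 303L, {
    nr <- ls$nrows; nc <- ls$ncols
    gap <- ls$gap_cols
    col_m <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    row_m <- matrix(rep(seq_len(nr), nc), nr, nc)
    # precipitation: dry west (~1300 mm) to moist east (~3800 mm), with a
    # dip over the gap band and noise
    precip <- 1300 + 2500 * (col_m - 1) / (nc - 1)
    precip[, gap] <- precip[, gap] - 500
    precip <- precip + matrix(rnorm(nr * nc, 0, 60), nr, nc)
    temp <- 27 - 3 * (row_m - 1) / (nr - 1) +
      matrix(rnorm(nr * nc, 0, 0.3), nr, nc)
    alt <- 1100 - 820 * (col_m - 1) / (nc - 1) +
      matrix(rnorm(nr * nc, 0, 20), nr, nc)
    precip_lgm <- precip - ls$lgm_precip_shift
    temp_lgm <- temp - 3
    truth_north <- exp(-((alt - 850) / 350)^2)
    truth_south <- stats::plogis((precip - 3300) / 300)
    mk <- function(m) raster_grid(m, xllcorner = -86, yllcorner = 8,
                                  cellsize = 0.1)
    sample_presences <- function(truth, cols_ok) {
      suit <- truth
      suit[, setdiff(seq_len(nc), cols_ok)] <- 0
      cand <- which(suit > 0.7, arr.ind = TRUE)
      take <- cand[sample.int(nrow(cand), min(ls$n_presence, nrow(cand))), ,
                   drop = FALSE]
      data.frame(row = take[, 1], col = take[, 2])
    }
    west <- seq_len(min(gap) - 1L)
    east <- seq(max(gap) + 1L, nc)
    gap_mask <- matrix(FALSE, nr, nc)
    gap_mask[, gap] <- TRUE
    list(current = climate_stack(precip = mk(precip), temp = mk(temp),
                                 alt = mk(alt)),
         lgm = climate_stack(precip = mk(precip_lgm), temp = mk(temp_lgm),
                             alt = mk(alt)),
         presences_north = sample_presences(truth_north, west),
         presences_south = sample_presences(truth_south, east),
         truth_north = mk(truth_north), truth_south = mk(truth_south),
         gap_mask = gap_mask, gap_cols = gap)
  })
}

#' Write all fixtures for a scenario to a directory
#'
#' Emits the external formats of the pipeline: STRUCTURE-format genotypes,
#' FASTA mtDNA, CSV locality table, and ESRI ASCII climate grids for both
#' periods.
#'
#' @param sc a \code{\link{scenario}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
write_scenario_fixtures <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ms <- simulate_microsatellites(sc)
  aln <- simulate_mtdna(sc)
  land <- simulate_landscape(sc)
  paths <- c(genotypes = file.path(dir, "genotypes.str"),
             mtdna = file.path(dir, "mtdna.fasta"),
             localities = file.path(dir, "localities.csv"))
  write_genotypes(ms$genotypes, paths["genotypes"])
  write_fasta(aln, paths["mtdna"])
  write.csv(ms$localities, paths["localities"], row.names = FALSE)
  for (per in c("current", "lgm"))
    for (ly in names(land[[per]])) {
      p <- file.path(dir, sprintf("%s_%s.asc", per, ly))
      write_ascii_grid(land[[per]][[ly]], p)
      paths[paste(per, ly, sep = "_")] <- p
    }
  invisible(paths)
}
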