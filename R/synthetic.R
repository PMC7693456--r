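#' Synthetic cohort configuration
#'
#' Defines the study conditions for the synthetic two-group cohort generator:
#' a 43-vs-43 patient/control design on a 19-node salience-network atlas,
#' 230 retained volumes at TR = 2 s, connectivity deficits planted on a
#' connected set of edges in the patient group, patient-only clinical
#' variables with the published marginal means/SDs (e.g. hemoglobin
#' 89.7 (22.3) g/L), per-group behavioral score distributions, and an
#' optional planted mediation structure (clinical variable X -> edge
#' connectivity M -> behavioral score Y).
#'
#' @param n_per_group subjects per group (>= 3).
#' @param n_nodes number of atlas nodes (default 19).
#' @param n_timepoints retained volumes per subject (default 230).
#' @param tr_seconds repetition time (default 2).
#' @param planted_edges data frame with columns \code{i}, \code{j},
#'   \code{delta_z}: Fisher-z connectivity deficits applied to the patient
#'   group. Default: a connected 5-edge deficit of 0.5 anchored on the
#'   anterior insulae (cluster-level inference detects connected effects;
#'   see the methods vignette). Use \code{NULL} for a null cohort.
#' @param mediation a \code{mediation_spec()} or \code{NULL} (no planted
#'   mediation).
#' @param subject_z_sd between-subject SD of each edge's Fisher-z
#'   connectivity around its group mean (default 0.15). Realized via a
#'   Wishart-type draw of \code{round(1/subject_z_sd^2) + 3} latent
#'   Gaussian samples per subject, which keeps every subject's base
#'   connectivity a valid correlation matrix.
#' @param timeseries logical; if \code{TRUE} each subject gets a sampled
#'   ROI time-series matrix (connectivity then carries genuine sampling
#'   noise), if \code{FALSE} Fisher-z connectivity matrices are generated
#'   directly with emulated sampling noise of SD \code{1/sqrt(T - 3)} —
#'   orders of magnitude faster for large simulation studies.
#' @param clinical_means_sds named list of \code{c(mean, sd)} per clinical
#'   variable (patients only; defaults from the published cohort table).
#' @param behavior_means_sds named list of per-variable
#'   \code{list(control = c(mean, sd), patient = c(mean, sd))}.
#' @param motion_step_mm,motion_step_rad random-walk step SDs for the
#'   simulated motion traces (defaults give mean FD near 0.18 mm).
#' @param seed integer seed; identical configs give byte-identical cohorts.
#' @return a \code{cohort_config} list.
#' @export
cohort_config <- function(n_per_group = 43L,
                          n_nodes = 19L,
                          n_timepoints = 230L,
                          tr_seconds = 2,
                          planted_edges = default_planted_edges(),
                          mediation = NULL,
                          subject_z_sd = 0.15,
                          timeseries = TRUE,
                          clinical_means_sds = default_clinical(),
                          behavior_means_sds = default_behavior(),
                          motion_step_mm = 0.04,
                          motion_step_rad = 8e-4,
                          seed = 1L) {
  if (n_per_group < 3L) stopf("n_per_group must be >= 3")
  if (n_nodes < 2L) stopf("n_nodes must be >= 2")
  if (is.null(planted_edges))
    planted_edges <- data.frame(i = integer(), j = integer(),
                                delta_z = numeric())
  planted_edges <- as.data.frame(planted_edges)
  if (nrow(planted_edges)) {
    stopifnot(all(c("i", "j", "delta_z") %in% names(planted_edges)))
    check_finite(planted_edges$delta_z, "delta_z")
    if (any(planted_edges$i == planted_edges$j))
      stopf("planted edges must connect distinct nodes")
    if (any(planted_edges$i < 1 | planted_edges$j < 1 |
            planted_edges$i > n_nodes | planted_edges$j > n_nodes))
      stopf("planted edge indices out of range")
  }
  if (!is.null(mediation) && !inherits(mediation, "mediation_spec"))
    stopf("mediation must be a mediation_spec() or NULL")
  structure(list(
    n_per_group = as.integer(n_per_group), n_nodes = as.integer(n_nodes),
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    planted_edges = planted_edges, mediation = mediation,
    subject_z_sd = subject_z_sd, timeseries = isTRUE(timeseries),
    clinical_means_sds = clinical_means_sds,
    behavior_means_sds = behavior_means_sds,
    motion_step_mm = motion_step_mm, motion_step_rad = motion_step_rad,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Planted mediation structure
#'
#' Structural coefficients for the generator's X -> M -> Y chain: X is a
#' patient clinical variable (standardized internally before the structural
#' equations, since e.g. hemoglobin has SD 22.3 g/L), M is the Fisher-z
#' connectivity of one designated edge, Y is a behavioral score.
#' \code{M = i_M + a X* + g'cov + e_M}; \code{Y = i_Y + c' X* + b M + g'cov
#' + e_Y}, with X* the standardized clinical variable.
#'
#' @param a,b,c_prime structural path coefficients.
#' @param noise_sd_M,noise_sd_Y residual SDs of the mediator and outcome.
#' @param edge length-2 integer vector: the mediator edge (node indices).
#' @param x_var,y_var names of the clinical X and behavioral Y variables.
#' @param covariate_effects list with numeric length-3 vectors \code{M} and
#'   \code{Y}: effects of (age decades, gender indicator, education years)
#'   on M and Y. Zero by default.
#' @return a \code{mediation_spec} list.
#' @export
mediation_spec <- function(a = 0.5, b = 0.4, c_prime = 0.1,
                           noise_sd_M = 0.2, noise_sd_Y = 0.5,
                           edge = c(1L, 3L),
                           x_var = "hemoglobin", y_var = "FDST",
                           covariate_effects = list(M = c(0, 0, 0),
                                                    Y = c(0, 0, 0))) {
  stopifnot(length(edge) == 2L, edge[1] != edge[2])
  structure(list(a = a, b = b, c_prime = c_prime,
                 noise_sd_M = noise_sd_M, noise_sd_Y = noise_sd_Y,
                 edge = as.integer(edge), x_var = x_var, y_var = y_var,
                 covariate_effects = covariate_effects),
            class = "mediation_spec")
}

#' @rdname cohort_config
#' @param delta_z planted Fisher-z deficit shared by the five default edges.
#' @export
default_planted_edges <- function(delta_z = 0.5) {
  # connected 5-edge set through the anterior insulae, all edges the
  # between-group comparison reports: dACC--AIS_L, AIS_L--AIS_R,
  # AIS_R--SMG_R, AIS_L--PIS_L, PIS_L--MCC_R
  data.frame(i = c(1L, 2L, 3L, 2L, 8L),
             j = c(2L, 3L, 11L, 8L, 12L),
             delta_z = delta_z)
}

default_clinical <- function() {
  list(hemoglobin = c(89.7, 22.3), serum_urea_nitrogen = c(19.1, 10.2),
       serum_creatinine = c(677.4, 294.1), triglyceride = c(1.9, 1.2),
       cholesterol = c(4.2, 1.0), low_density_lipoprotein = c(2.3, 0.7))
}

default_behavior <- function() {
  list(MoCA  = list(control = c(26, 3),    patient = c(23, 5)),
       TMT_A = list(control = c(56, 27),   patient = c(76, 29)),
       TMT_B = list(control = c(68, 35),   patient = c(97, 55)),
       FDST  = list(control = c(6.9, 1.5), patient = c(5.3, 1.4)),
       BDST  = list(control = c(5.9, 1.6), patient = c(4.9, 1.2)),
       SDMT  = list(control = c(50, 14),   patient = c(41, 10)),
       HAMA  = list(control = c(5.1, 3.5), patient = c(8.3, 7.1)),
       HAMD  = list(control = c(4.6, 3.9), patient = c(11.5, 7.4)))
}

# Population Fisher-z connectivity for the control group: moderate
# connectivity within each subnetwork, weaker across, and a strongly
# connected insula/dACC core (the edges the between-group comparison
# highlights). The strong core keeps the planted-deficit population
# matrices positive definite: a 0.5 deficit on a z = 0.6 edge leaves it at
# 0.1 instead of forcing an infeasible negative correlation inside a
# positively coupled network (which would make the eigenvalue-clipping
# repair systematically undo part of the plant).
base_population_z <- function(atlas) {
  n <- nrow(atlas)
  ant <- atlas$subnetwork == "anterior"
  z <- matrix(0.15, n, n)
  z[ant, ant] <- 0.30
  z[!ant, !ant] <- 0.30
  if (n == 19L) {
    hub <- cbind(i = c(1L, 2L, 3L, 2L, 8L, 1L),
                 j = c(2L, 3L, 11L, 8L, 12L, 3L))
    z[hub] <- 0.60
    z[hub[, 2:1]] <- 0.60
  }
  diag(z) <- 0
  z
}

#' Nearest-correlation repair by eigenvalue clipping
#'
#' Clips eigenvalues below \code{floor}, reconstructs and rescales to unit
#' diagonal, iterating until the matrix is a valid correlation matrix.
#'
#' @param m symmetric matrix with unit diagonal (a would-be correlation
#'   matrix).
#' @param floor smallest admissible eigenvalue.
#' @param maxit maximum clip-rescale iterations.
#' @return a positive-definite correlation matrix.
#' @export
nearest_corr <- function(m, floor = 1e-6, maxit = 100L) {
  for (it in seq_len(maxit)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= floor) return(m)
    v <- pmax(e$values, floor)
    m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / outer(d, d)
    diag(m) <- 1
    m <- (m + t(m)) / 2
  }
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < floor / 2)
    stopf("target correlation matrix not repairable to positive definite")
  m
}

#' Generate a synthetic two-group cohort
#'
#' Draws a complete cohort under the configured study conditions: balanced
#' patient/control groups sharing one node order, per-subject Fisher-z
#' connectivity equal to the group population matrix plus between-subject
#' jitter (patients carry the planted deficits), optional stationary
#' Gaussian ROI time series realizing each subject's target correlation
#' matrix, random-walk motion traces, patient clinical variables, and
#' behavioral scores — with the designated outcome generated from the
#' planted mediation structure when one is configured.
#'
#' @param config a \code{cohort_config()}.
#' @return an \code{sn_cohort}: list with \code{subjects} (metadata data
#'   frame), \code{timeseries} (named list of timepoint x node matrices, or
#'   \code{NULL}), \code{connectivity} (named list of \code{conn_matrix},
#'   matrix mode only), \code{motion} (named list), \code{atlas}, and
#'   \code{ground_truth} (the config plus per-subject true mediator values).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = 5, seed = 7,
#'                                         timeseries = FALSE))
#' table(cohort$subjects$group)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  atlas <- sn_atlas()
  if (cfg$n_nodes != nrow(atlas)) {
    atlas <- data.frame(node_id = seq_len(cfg$n_nodes),
                        label = sprintf("node_%02d", seq_len(cfg$n_nodes)),
                        subnetwork = rep(c("anterior", "posterior"),
                                         length.out = cfg$n_nodes),
                        x = NA_real_, y = NA_real_, z = NA_real_)
    class(atlas) <- c("sn_atlas", "data.frame")
  }
  n <- cfg$n_per_group
  n_sub <- 2L * n
  group <- rep(c("patient", "control"), each = n)
  ids <- sprintf("sub-%03d", seq_len(n_sub))

  # demographics (patient / control marginals from the study table)
  age <- ifelse(group == "patient", stats::rnorm(n_sub, 47, 10),
                stats::rnorm(n_sub, 46, 10))
  age <- pmax(age, 18)
  n_male <- round(n * 24 / 43)
  gender <- c(rep(c("M", "F"), c(n_male, n - n_male)),
              rep(c("M", "F"), c(n_male, n - n_male)))
  education <- pmax(ifelse(group == "patient", stats::rnorm(n_sub, 9.6, 3.0),
                           stats::rnorm(n_sub, 10.8, 4.1)), 0)

  subjects <- data.frame(subject_id = ids, group = group, age = age,
                         gender = gender, education = education,
                         stringsAsFactors = FALSE)

  # clinical variables: patients only (as in the study design)
  for (v in names(cfg$clinical_means_sds)) {
    ms <- cfg$clinical_means_sds[[v]]
    subjects[[v]] <- ifelse(group == "patient",
                            stats::rnorm(n_sub, ms[1], ms[2]), NA_real_)
  }

  # group population z matrices
  z_control <- base_population_z(atlas)
  z_patient <- z_control
  if (nrow(cfg$planted_edges)) {
    for (k in seq_len(nrow(cfg$planted_edges))) {
      i <- cfg$planted_edges$i[k]; j <- cfg$planted_edges$j[k]
      z_patient[i, j] <- z_patient[i, j] - cfg$planted_edges$delta_z[k]
      z_patient[j, i] <- z_patient[i, j]
    }
  }

  med <- cfg$mediation
  x_std <- rep(NA_real_, n_sub)
  m_true <- rep(NA_real_, n_sub)
  gender01 <- as.numeric(subjects$gender == "M")
  if (!is.null(med)) {
    xv <- subjects[[med$x_var]]
    if (is.null(xv)) stopf("mediation x_var '%s' not generated", med$x_var)
    pat <- group == "patient"
    x_std[pat] <- (xv[pat] - mean(xv[pat])) / stats::sd(xv[pat])
  }

  # Per-subject target z matrices. Between-subject variability is a
  # Wishart-type draw: each subject's base connectivity is the sample
  # correlation of m latent Gaussian vectors from the group population
  # matrix, so it is a valid correlation matrix by construction and its
  # edge-wise Fisher-z SD is ~ 1/sqrt(m - 3) = subject_z_sd. Only the
  # mediation edge is overridden afterwards (structural equation), which
  # leaves at most a one-edge feasibility violation for the repair step.
  n_nodes <- cfg$n_nodes
  edges <- edge_table(n_nodes)
  n_edges <- nrow(edges)
  m_df <- max(round(1 / cfg$subject_z_sd^2) + 3L, n_nodes + 2L)
  chol_pop <- list(
    patient = chol(nearest_corr(`diag<-`(tanh(z_patient), 1))),
    control = chol(nearest_corr(`diag<-`(tanh(z_control), 1))))
  target_z <- matrix(NA_real_, n_sub, n_edges)
  for (s in seq_len(n_sub)) {
    base <- if (group[s] == "patient") z_patient else z_control
    G <- matrix(stats::rnorm(m_df * n_nodes), m_df, n_nodes) %*%
      chol_pop[[group[s]]]
    W <- stats::cor(G)
    W <- pmin(pmax(W, -(1 - 1e-7)), 1 - 1e-7)
    zs <- atanh(flatten_edges(W, edges))
    if (!is.null(med) && group[s] == "patient") {
      ke <- which((edges$i == min(med$edge) & edges$j == max(med$edge)))
      cov_m <- sum(med$covariate_effects$M *
                     c(age[s] / 10, gender01[s], education[s]))
      zs[ke] <- flatten_edges(base, edges)[ke] + med$a * x_std[s] + cov_m +
        stats::rnorm(1, 0, med$noise_sd_M)
      m_true[s] <- zs[ke]
    }
    target_z[s, ] <- zs
  }

  # behavioral scores; the mediation outcome follows the structural model
  for (v in names(cfg$behavior_means_sds)) {
    bs <- cfg$behavior_means_sds[[v]]
    subjects[[v]] <- ifelse(group == "patient",
                            stats::rnorm(n_sub, bs$patient[1], bs$patient[2]),
                            stats::rnorm(n_sub, bs$control[1], bs$control[2]))
  }
  if (!is.null(med)) {
    pat <- which(group == "patient")
    i_y <- cfg$behavior_means_sds[[med$y_var]]$patient[1]
    cov_y <- med$covariate_effects$Y[1] * age[pat] / 10 +
      med$covariate_effects$Y[2] * gender01[pat] +
      med$covariate_effects$Y[3] * education[pat]
    subjects[[med$y_var]][pat] <- i_y + med$c_prime * x_std[pat] +
      med$b * m_true[pat] + cov_y +
      stats::rnorm(length(pat), 0, med$noise_sd_Y)
  }

  timeseries <- NULL; connectivity <- NULL; motion <- list()
  if (cfg$timeseries) {
    timeseries <- vector("list", n_sub)
    names(timeseries) <- ids
    for (s in seq_len(n_sub)) {
      r <- unflatten_edges(tanh(target_z[s, ]), n_nodes, edges)
      diag(r) <- 1
      r <- nearest_corr(r)
      L <- chol(r)
      ts <- matrix(stats::rnorm(cfg$n_timepoints * n_nodes),
                   cfg$n_timepoints, n_nodes) %*% L
      colnames(ts) <- atlas$label
      attr(ts, "tr_seconds") <- cfg$tr_seconds
      timeseries[[s]] <- ts
    }
  } else {
    # emulate correlation sampling noise at the configured series length
    samp_sd <- 1 / sqrt(cfg$n_timepoints - 3)
    connectivity <- vector("list", n_sub)
    names(connectivity) <- ids
    for (s in seq_len(n_sub)) {
      zr <- target_z[s, ] + stats::rnorm(n_edges, 0, samp_sd)
      vals <- unflatten_edges(zr, n_nodes, edges)
      dimnames(vals) <- list(atlas$label, atlas$label)
      connectivity[[s]] <- conn_matrix(vals, "fisher_z", ids[s])
    }
  }
  for (s in seq_len(n_sub))
    motion[[ids[s]]] <- generate_motion(cfg$n_timepoints,
                                        seed = NULL,
                                        step_mm = cfg$motion_step_mm,
                                        step_rad = cfg$motion_step_rad)

  truth <- list(config = cfg, m_true = m_true, x_std = x_std,
                population_z = list(patient = z_patient,
                                    control = z_control))
  structure(list(subjects = subjects, timeseries = timeseries,
                 connectivity = connectivity, motion = motion,
                 atlas = atlas, ground_truth = truth),
            class = "sn_cohort")
}

#' Generate random-walk head-motion traces
#'
#' Six-parameter rigid-body motion as independent Gaussian random walks:
#' three translations (mm) and three rotations (radians).
#'
#' @param n_volumes number of volumes (>= 2).
#' @param seed integer seed, or \code{NULL} to use the current RNG stream
#'   (as the cohort generator does).
#' @param step_mm,step_rad per-step SDs of the translation and rotation
#'   increments.
#' @return a volumes x 6 matrix (columns tx, ty, tz, rx, ry, rz).
#' @export
generate_motion <- function(n_volumes, seed = NULL, step_mm = 0.04,
                            step_rad = 8e-4) {
  if (n_volumes < 2L) stopf("n_volumes must be >= 2")
  gen <- function() {
    steps <- cbind(matrix(stats::rnorm(3 * (n_volumes - 1), 0, step_mm),
                          n_volumes - 1, 3),
                   matrix(stats::rnorm(3 * (n_volumes - 1), 0, step_rad),
                          n_volumes - 1, 3))
    m <- rbind(0, apply(steps, 2L, cumsum))
    colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    m
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @export
print.sn_cohort <- function(x, ...) {
  cfg <- x$ground_truth$config
  cat(sprintf("Synthetic cohort: %d patients vs %d controls, %d nodes",
              sum(x$subjects$group == "patient"),
              sum(x$subjects$group == "control"), cfg$n_nodes))
  cat(if (cfg$timeseries)
    sprintf(", %d timepoints (TR %gs)\n", cfg$n_timepoints, cfg$tr_seconds)
    else ", connectivity matrices\n")
  if (nrow(cfg$planted_edges))
    cat(sprintf("Planted deficit on %d edge(s), delta_z = %s\n",
                nrow(cfg$planted_edges),
                paste(unique(cfg$planted_edges$delta_z), collapse = ", ")))
  if (!is.null(cfg$mediation))
    cat(sprintf("Planted mediation: %s -> edge(%d,%d) -> %s (a=%g, b=%g, c'=%g)\n",
                cfg$mediation$x_var, cfg$mediation$edge[1],
                cfg$mediation$edge[2], cfg$mediation$y_var,
                cfg$mediation$a, cfg$mediation$b, cfg$mediation$c_prime))
  invisible(x)
}
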