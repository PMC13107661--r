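#' Default chronic-disease catalog
#'
#' A synthetic catalog of 33 chronic conditions organised into four planted
#' disease groups (cardiovascular, neuropsychiatric, respiratory-digestive,
#' metabolic-pain) plus two bridge diseases that connect groups. Three
#' conditions are given baseline prevalences below the 1% pooled-prevalence
#' exclusion line, so that the default inclusion filter retains 30 diseases.
#' One disease per block is flagged as the block hub (clinically dominant
#' condition with dense connections inside its group).
#'
#' @return A `data.frame` with columns `code`, `name`, `block` (community
#'   index 1..K or `"bridge"`), `base_prevalence` (baseline fraction in the
#'   youngest stratum) and `hub` (logical).
#' @export
default_catalog <- function() {
  x <- rbind(
    # block 1: cardiovascular
    c("hf",   "heart_failure",               "1", 0.030, TRUE),
    c("htn",  "hypertension",                "1", 0.330, FALSE),
    c("ihd",  "ischemic_heart_disease",      "1", 0.100, FALSE),
    c("arr",  "cardiac_arrhythmias",         "1", 0.060, FALSE),
    c("vhd",  "valvular_heart_disease",      "1", 0.030, FALSE),
    c("pvd",  "peripheral_vascular_disease", "1", 0.040, FALSE),
    c("crf",  "chronic_renal_failure",       "1", 0.030, FALSE),
    # block 2: neuropsychiatric
    c("dem",  "dementia",                    "2", 0.025, TRUE),
    c("park", "parkinsons_disease",          "2", 0.015, FALSE),
    c("epi",  "epilepsy",                    "2", 0.015, FALSE),
    c("dep",  "depression_anxiety",          "2", 0.120, FALSE),
    c("psy",  "psychotic_disorders",         "2", 0.020, FALSE),
    c("mig",  "migraine",                    "2", 0.050, FALSE),
    c("ms",   "multiple_sclerosis",          "2", 0.0012, FALSE),
    c("neur", "peripheral_neuropathy",       "2", 0.030, FALSE),
    # block 3: respiratory-digestive
    c("copd", "copd",                        "3", 0.080, TRUE),
    c("ast",  "asthma",                      "3", 0.050, FALSE),
    c("bre",  "bronchiectasis",              "3", 0.0012, FALSE),
    c("ulc",  "peptic_ulcer",                "3", 0.040, FALSE),
    c("ibd",  "inflammatory_bowel_disease",  "3", 0.015, FALSE),
    c("div",  "diverticular_disease",        "3", 0.050, FALSE),
    c("hep",  "chronic_hepatitis",           "3", 0.020, FALSE),
    c("cir",  "cirrhosis",                   "3", 0.015, FALSE),
    # block 4: metabolic-pain
    c("diab", "diabetes",                    "4", 0.150, TRUE),
    c("thy",  "thyroid_disorders",           "4", 0.100, FALSE),
    c("obe",  "obesity",                     "4", 0.100, FALSE),
    c("dys",  "dyslipidemia",                "4", 0.200, FALSE),
    c("ost",  "osteoporosis",                "4", 0.080, FALSE),
    c("rhe",  "rheumatologic_conditions",    "4", 0.060, FALSE),
    c("pag",  "pagets_disease",              "4", 0.012, FALSE),
    c("lup",  "systemic_lupus",              "4", 0.0012, FALSE),
    # bridges
    c("cvd",  "cerebrovascular_disease",     "bridge", 0.050, FALSE),
    c("neo",  "neoplasms",                   "bridge", 0.080, FALSE)
  )
  data.frame(
    code = x[, 1], name = x[, 2], block = x[, 3],
    base_prevalence = as.numeric(x[, 4]), hub = as.logical(x[, 5]),
    stringsAsFactors = FALSE
  )
}

#' Generate a disease catalog
#'
#' Builds a catalog of `p` diseases partitioned into `K` planted blocks plus
#' `n_bridge` designated bridge diseases. With the default arguments the
#' 33-disease fixture from [default_catalog()] is returned. For other sizes a
#' deterministic synthetic catalog is constructed: diseases are dealt
#' round-robin into blocks, the first disease of each block is its hub, and
#' prevalences follow a geometric profile between `prevalence_range`. The
#' last `n_rare` non-hub diseases receive `rare_prevalence`, placing them
#' below the default pooled-prevalence exclusion line.
#'
#' @param p Number of diseases (block members + bridges).
#' @param K Number of planted blocks (>= 2 unless `p == K`).
#' @param n_bridge Number of bridge diseases (may be 0).
#' @param n_rare Number of diseases given `rare_prevalence`.
#' @param prevalence_range Range of the geometric baseline prevalence profile.
#' @param rare_prevalence Baseline prevalence assigned to rare diseases.
#' @return A catalog `data.frame`; see [default_catalog()].
#' @export
generate_catalog <- function(p = 33, K = 4, n_bridge = 2, n_rare = 3,
                             prevalence_range = c(0.015, 0.30),
                             rare_prevalence = 0.002) {
  if (p == 33 && K == 4 && n_bridge == 2 && n_rare == 3 &&
      identical(prevalence_range, c(0.015, 0.30)))
    return(default_catalog())
  if (!is.numeric(p) || !is.numeric(K) || p < 1 || K < 1)
    stop("invalid catalog config: p and K must be positive integers")
  if (p < K)
    stop("invalid catalog config: p must be >= K")
  if (n_bridge < 0 || p - n_bridge < K)
    stop("invalid catalog config: p - n_bridge must be >= K")
  n_block <- p - n_bridge
  blocks <- rep(seq_len(K), length.out = n_block)
  blocks <- sort(blocks)
  code <- sprintf("d%02d", seq_len(p))
  block <- c(as.character(blocks), rep("bridge", n_bridge))
  hub <- c(!duplicated(blocks), rep(FALSE, n_bridge))
  prev <- exp(seq(log(prevalence_range[2]), log(prevalence_range[1]),
                  length.out = p))
  if (n_rare > 0) {
    cand <- rev(which(!hub))
    rare_idx <- cand[seq_len(min(n_rare, length(cand)))]
    prev[rare_idx] <- rare_prevalence
  }
  data.frame(code = code, name = code, block = block,
             base_prevalence = prev, hub = hub, stringsAsFactors = FALSE)
}

#' Planted Ising coupling matrix for a catalog
#'
#' Builds the symmetric pairwise-coupling matrix of the planted disease
#' dependence model. Each block hub is connected to every member of its
#' block; remaining within-block pairs are connected independently with
#' probability `within_density`. Bridge diseases are connected to
#' `n_anchor` members (always including the hub) of each of `bridge_span`
#' blocks (non-overlapping pairs in rotation; `"all"` anchors every
#' block). A fraction `negative_frac` of non-hub within-block couplings is
#' made negative.
#'
#' @param catalog A catalog `data.frame` (see [generate_catalog()]).
#' @param within Coupling magnitude for within-block edges.
#' @param bridge Coupling magnitude for bridge edges.
#' @param background Coupling for all remaining pairs (default 0).
#' @param within_density Probability of a non-hub within-block edge.
#' @param negative_frac Fraction of non-hub within-block edges with
#'   negative sign.
#' @param nonhub_scale Multiplier on the magnitude of non-hub within-block
#'   edges (1 = same as hub edges; smaller values give hub-dominated,
#'   star-like blocks).
#' @param n_anchor Number of members per block a bridge disease attaches to.
#' @param bridge_span Number of blocks each bridge anchors (default 2), or
#'   `"all"`.
#' @param seed Optional seed for the random within-block structure.
#' @return A symmetric `p x p` matrix with zero diagonal, with dimnames set
#'   to the disease codes.
#' @export
planted_coupling <- function(catalog, within = 0.6, bridge = 0.45,
                             background = 0, within_density = 0.35,
                             negative_frac = 0.1, nonhub_scale = 1,
                             n_anchor = 3, bridge_span = 2,
                             seed = NULL) {
  stopifnot(is.data.frame(catalog), all(c("code", "block", "hub") %in%
                                          names(catalog)))
  with_seed(seed, {
    p <- nrow(catalog)
    theta <- matrix(background, p, p,
                    dimnames = list(catalog$code, catalog$code))
    diag(theta) <- 0
    blocks <- setdiff(unique(catalog$block), "bridge")
    for (b in blocks) {
      idx <- which(catalog$block == b)
      hub <- idx[catalog$hub[idx]][1]
      if (is.na(hub)) hub <- idx[1]
      for (j in setdiff(idx, hub)) theta[hub, j] <- theta[j, hub] <- within
      others <- setdiff(idx, hub)
      if (length(others) >= 2) {
        pairs <- utils::combn(others, 2)
        for (k in seq_len(ncol(pairs))) {
          if (runif(1) < within_density) {
            s <- if (runif(1) < negative_frac) -1 else 1
            i <- pairs[1, k]; j <- pairs[2, k]
            theta[i, j] <- theta[j, i] <- s * within * nonhub_scale
          }
        }
      }
    }
    br <- which(catalog$block == "bridge")
    if (length(br) > 0 && length(blocks) >= 2) {
      K <- length(blocks)
      for (k in seq_along(br)) {
        span <- if (identical(bridge_span, "all")) blocks else
          blocks[((2 * (k - 1) + seq_len(bridge_span) - 1) %% K) + 1]
        for (b in span) {
          idx <- which(catalog$block == b)
          hub <- idx[catalog$hub[idx]][1]
          if (is.na(hub)) hub <- idx[1]
          anchors <- unique(c(hub, idx[seq_len(min(n_anchor, length(idx)))]))
          anchors <- anchors[seq_len(min(n_anchor, length(anchors)))]
          for (j in anchors) theta[br[k], j] <- theta[j, br[k]] <- bridge
        }
      }
    }
    theta
  })
}

#' Planted community membership of a catalog
#'
#' Returns the planted block index of each disease; bridge diseases are
#' attributed to the first block they anchor to (matching the rotation used
#' by [planted_coupling()]).
#'
#' @param catalog A catalog `data.frame`.
#' @return Named integer vector of block memberships.
#' @export
planted_membership <- function(catalog) {
  blocks <- setdiff(unique(catalog$block), "bridge")
  m <- integer(nrow(catalog))
  names(m) <- catalog$code
  for (i in seq_len(nrow(catalog))) {
    if (catalog$block[i] == "bridge") {
      k <- sum(catalog$block[seq_len(i)] == "bridge")
      m[i] <- match(blocks[((k - 1) %% length(blocks)) + 1], blocks)
    } else {
      m[i] <- match(catalog$block[i], blocks)
    }
  }
  m
}

#' Simulate a planted-block disease study
#'
#' One-call fixture for method validation: builds a catalog of `p`
#' diseases in `K` planted blocks (optionally with bridge diseases),
#' the planted coupling matrix, mean-field-calibrated intercepts, and a
#' sample of `n` rows from the Ising model. The default prevalence
#' profile spans 0.05-0.30 so every disease carries enough signal for
#' structure recovery at moderate n.
#'
#' @param p,K,n_bridge Catalog dimensions (see [generate_catalog()]).
#' @param n Sample size.
#' @param within,bridge,within_density,negative_frac,nonhub_scale,bridge_span
#'   Coupling parameters (see [planted_coupling()]).
#' @param prevalence_range Prevalence profile of the catalog.
#' @param seed Seed (drives both the random block structure and the
#'   Gibbs draw).
#' @return List: `catalog`, `theta` (coupling matrix), `membership`
#'   (planted blocks), `X` (`n x p` binary matrix).
#' @export
simulate_planted_blocks <- function(p = 30, K = 4, n = 20000,
                                    n_bridge = 0, within = 0.8,
                                    bridge = 0.5, within_density = 0.6,
                                    negative_frac = 0.05, nonhub_scale = 1,
                                    bridge_span = 2,
                                    prevalence_range = c(0.05, 0.30),
                                    seed = 1) {
  cat0 <- generate_catalog(p = p, K = K, n_bridge = n_bridge, n_rare = 0,
                           prevalence_range = prevalence_range)
  theta <- planted_coupling(cat0, within = within, bridge = bridge,
                            within_density = within_density,
                            negative_frac = negative_frac,
                            nonhub_scale = nonhub_scale,
                            bridge_span = bridge_span,
                            seed = child_seed(seed, "structure"))
  h <- calibrate_intercepts(theta, cat0$base_prevalence, refine = 0)
  X <- sample_ising(theta, h, n, seed = child_seed(seed, "draw"))
  list(catalog = cat0, theta = theta,
       membership = planted_membership(cat0), X = X)
}
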