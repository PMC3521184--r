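# Small models and independent oracles used across the suite.

# linear chain: EX_a (uptake <= cap) -> T_a -> R1 -> R_bio -> EX_bio
chain_model <- function(cap = 10) {
  met <- tibble::tibble(id = c("a_ext", "a_c", "b_c", "bio_ext"),
                        compartment = c("ext", "M.cytosol", "M.cytosol", "ext"))
  rxn <- tibble::tibble(
    id = c("EX_a", "T_a", "R1", "R_bio", "EX_bio"),
    lower_bound = c(-cap, 0, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000, 1000))
  sto <- tibble::tibble(
    reaction_id = c("EX_a", "T_a", "T_a", "R1", "R1", "R_bio", "R_bio", "EX_bio"),
    metabolite_id = c("a_ext", "a_ext", "a_c", "a_c", "b_c", "b_c", "bio_ext",
                      "bio_ext"),
    coefficient = c(-1, -1, 1, -1, 1, -1, 1, -1))
  stoich_model(met, rxn, sto, c(EX_bio = 1), "chain")
}

# diamond: uptake of a (<= supply), two parallel conversion routes a -> b
# capped at 5 each, b exported
diamond_model <- function(supply = 8, branch_cap = 5) {
  met <- tibble::tibble(id = c("a_ext", "a_c", "b_c", "b_ext"),
                        compartment = c("ext", "M.cytosol", "M.cytosol", "ext"))
  rxn <- tibble::tibble(
    id = c("EX_a", "T_a", "R_up", "R_down", "T_b", "EX_b"),
    lower_bound = c(-supply, 0, 0, 0, 0, 0),
    upper_bound = c(0, 1000, branch_cap, branch_cap, 1000, 1000))
  sto <- tibble::tibble(
    reaction_id = c("EX_a", "T_a", "T_a", "R_up", "R_up", "R_down", "R_down",
                    "T_b", "T_b", "EX_b"),
    metabolite_id = c("a_ext", "a_ext", "a_c", "a_c", "b_c", "a_c", "b_c",
                      "b_c", "b_ext", "b_ext"),
    coefficient = c(-1, -1, 1, -1, 1, -1, 1, -1, 1, -1))
  stoich_model(met, rxn, sto, c(EX_b = 1), "diamond")
}

# n fully parallel identical paths from one substrate to one product
parallel_model <- function(n_paths = 3, supply = 6) {
  met <- tibble::tibble(id = c("a_ext", "a_c", "b_c", "b_ext"),
                        compartment = c("ext", "M.cytosol", "M.cytosol", "ext"))
  path_ids <- paste0("R", seq_len(n_paths))
  rxn <- tibble::tibble(
    id = c("EX_a", "T_a", path_ids, "T_b", "EX_b"),
    lower_bound = c(-supply, 0, rep(0, n_paths), 0, 0),
    upper_bound = c(0, 1000, rep(1000, n_paths), 1000, 1000))
  sto <- dplyr::bind_rows(
    tibble::tibble(reaction_id = "EX_a", metabolite_id = "a_ext",
                   coefficient = -1),
    tibble::tibble(reaction_id = "T_a", metabolite_id = c("a_ext", "a_c"),
                   coefficient = c(-1, 1)),
    dplyr::bind_rows(lapply(path_ids, function(id) {
      tibble::tibble(reaction_id = id, metabolite_id = c("a_c", "b_c"),
                     coefficient = c(-1, 1))
    })),
    tibble::tibble(reaction_id = "T_b", metabolite_id = c("b_c", "b_ext"),
                   coefficient = c(-1, 1)),
    tibble::tibble(reaction_id = "EX_b", metabolite_id = "b_ext",
                   coefficient = -1))
  stoich_model(met, rxn, sto, c(EX_b = 1), "parallel")
}

# 1-D segment: a single free flux 0..cap runs through a 3-reaction chain
segment_model <- function(cap = 10) chain_model(cap = cap)

# Brute-force LP oracle by vertex enumeration: max/min c'v over
# {Sv = 0, l <= v <= u}. A vertex has d = n - rank(S) variables pinned at a
# bound; the rest solve the balance equations. Independent of the simplex
# code path.
brute_lp <- function(model, cvec, maximize = TRUE) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  cv <- stats::setNames(rep(0, n), colnames(S))
  cv[names(cvec)] <- cvec
  d <- n - qr(S)$rank
  best <- NULL
  check <- function(v) {
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) return()
    if (max(abs(S %*% v)) > 1e-7) return()
    val <- sum(cv * v)
    if (is.null(best) || (maximize && val > best) || (!maximize && val < best)) {
      best <<- val
    }
  }
  if (d == 0) {
    v <- qr.solve(S, rep(0, nrow(S)))
    check(v)
  } else {
    combos <- utils::combn(n, d)
    for (ci in seq_len(ncol(combos))) {
      pin <- combos[, ci]
      free <- setdiff(seq_len(n), pin)
      Sf <- S[, free, drop = FALSE]
      if (qr(Sf)$rank < length(free)) next
      for (mask in 0:(2^d - 1)) {
        at_ub <- bitwAnd(mask, 2^(seq_len(d) - 1)) > 0
        vp <- ifelse(at_ub, ub[pin], lb[pin])
        rhs <- -S[, pin, drop = FALSE] %*% vp
        vf <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
        if (is.null(vf)) next
        v <- numeric(n)
        v[pin] <- vp
        v[free] <- vf
        check(v)
      }
    }
  }
  best
}

# random small feasible FBA problem (0 always feasible: bounds straddle 0)
random_model <- function(seed, n_rxn = 6, n_met = 3) {
  withr::local_seed(seed)
  repeat {
    S <- matrix(sample(c(-1, 0, 0, 1, 2), n_met * n_rxn, replace = TRUE),
                n_met, n_rxn)
    if (all(colSums(abs(S)) > 0) && all(rowSums(abs(S)) > 0)) break
  }
  met <- tibble::tibble(id = c(paste0("m", seq_len(n_met)), "x_ext"),
                        compartment = c(rep("M.cytosol", n_met), "ext"))
  # append an exchange touching an ext species to satisfy the model contract
  S <- cbind(S, 0)
  S <- rbind(S, c(rep(0, n_rxn), -1))
  rxn <- tibble::tibble(id = paste0("r", seq_len(n_rxn + 1)),
                        lower_bound = c(round(stats::runif(n_rxn, -3, 0), 1), -1),
                        upper_bound = c(round(stats::runif(n_rxn, 0, 3), 1), 1))
  sto <- dplyr::bind_rows(lapply(seq_len(n_rxn + 1), function(j) {
    nz <- which(S[, j] != 0)
    tibble::tibble(reaction_id = paste0("r", j),
                   metabolite_id = met$id[nz], coefficient = S[nz, j])
  }))
  w <- round(stats::runif(n_rxn, -2, 2), 1)
  stoich_model(met, rxn, sto, stats::setNames(w, paste0("r", seq_len(n_rxn))),
               "random")
}
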