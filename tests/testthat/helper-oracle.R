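# Hand-written ODE right-hand side for the packaged model (independent of the
# compiled reaction engine). n coupled cells, ring/segment adjacency, VEGF bath.
# y: stacked per-cell vectors of the 16 ODE species (model order, no env/filo).
ode_species <- c("notch1_mRNA", "notch1", "dll4_mRNA", "dll4", "nicd",
                 "cis_complex", "trans_complex", "vegfr1_mRNA", "svegfr1_mRNA",
                 "mvegfr1", "mvegfr1_bound", "svegfr1_internal", "vegfr2_mRNA",
                 "vegfr2", "vegfr2_bound", "vegfr2_active")

fact <- function(mod, a, m0, h) 1 / a + (1 - 1 / a) * mod^h / (mod^h + m0^h)
frep <- function(mod, a, m0, h) 1 / a + (1 - 1 / a) * m0^h / (mod^h + m0^h)

oracle_rhs <- function(t, y, pars) {
  P <- pars$P          # list of per-cell parameter vectors
  nb <- pars$neighbors # list of neighbor index vectors
  V <- pars$vegf_bath
  n <- length(nb)
  Y <- matrix(y, nrow = n, byrow = TRUE,
              dimnames = list(NULL, ode_species))
  dY <- matrix(0, n, length(ode_species), dimnames = list(NULL, ode_species))
  deg_cnt <- vapply(nb, length, 1L)
  for (i in seq_len(n)) {
    p <- P[[i]]
    x <- Y[i, ]
    h <- p[["hill_h"]]
    dll4nb <- sum(Y[nb[[i]], "dll4"] / deg_cnt[nb[[i]]])
    trans <- p[["kt"]] * x[["notch1"]] * dll4nb
    cis <- p[["kc"]] * x[["notch1"]] * x[["dll4"]]
    # dll4 consumed on this cell by every neighbor's trans binding
    dll4_drain <- if (length(nb[[i]]) == 0) 0 else
      sum(vapply(nb[[i]], function(j)
        P[[j]][["kt"]] * Y[j, "notch1"], 1)) * x[["dll4"]] / deg_cnt[i]
    v_n1 <- p[["vmax_tc_notch1"]] *
      fact(x[["nicd"]], p[["a_notch1_nicd"]], p[["m0_notch1_nicd"]], h) *
      fact(x[["notch1"]], p[["a_notch1_auto"]], p[["m0_notch1_auto"]], h)
    v_d4 <- p[["vmax_tc_dll4"]] *
      fact(x[["vegfr2_bound"]] + x[["vegfr2_active"]],
           p[["a_dll4_vegfr2"]], p[["m0_dll4_vegfr2"]], h)
    v_r1 <- p[["vmax_tc_vegfr1"]] *
      fact(x[["nicd"]], p[["a_vegfr1_nicd"]], p[["m0_vegfr1_nicd"]], h)
    v_s1 <- p[["vmax_tc_svegfr1"]] *
      fact(x[["nicd"]], p[["a_svegfr1_nicd"]], p[["m0_svegfr1_nicd"]], h)
    v_r2 <- p[["vmax_tc_vegfr2"]] *
      frep(x[["nicd"]], p[["a_vegfr2_nicd"]], p[["m0_vegfr2_nicd"]], h)
    dY[i, "notch1_mRNA"] <- v_n1 - p[["k_deg_notch1_mrna"]] * x[["notch1_mRNA"]]
    dY[i, "notch1"] <- p[["k_tl_notch1"]] * x[["notch1_mRNA"]] -
      p[["k_deg_notch1"]] * x[["notch1"]] - trans - cis
    dY[i, "dll4_mRNA"] <- v_d4 - p[["k_deg_dll4_mrna"]] * x[["dll4_mRNA"]]
    dY[i, "dll4"] <- p[["k_tl_dll4"]] * x[["dll4_mRNA"]] -
      p[["k_deg_dll4"]] * x[["dll4"]] - cis - dll4_drain
    dY[i, "nicd"] <- p[["k_nicd_release"]] * x[["trans_complex"]] -
      p[["k_nicd_degradation"]] * x[["nicd"]]
    dY[i, "cis_complex"] <- cis - p[["k_deg_cis"]] * x[["cis_complex"]]
    dY[i, "trans_complex"] <- trans - p[["k_nicd_release"]] * x[["trans_complex"]]
    dY[i, "vegfr1_mRNA"] <- v_r1 - p[["k_deg_vegfr1_mrna"]] * x[["vegfr1_mRNA"]]
    dY[i, "svegfr1_mRNA"] <- v_s1 - p[["k_deg_vegfr1_mrna"]] * x[["svegfr1_mRNA"]]
    dY[i, "mvegfr1"] <- p[["k_tl_mvegfr1"]] * x[["vegfr1_mRNA"]] -
      p[["k_deg_receptor"]] * x[["mvegfr1"]] -
      p[["k_on_mvegfr1"]] * x[["mvegfr1"]] * V +
      p[["k_off_mvegfr1"]] * x[["mvegfr1_bound"]]
    dY[i, "mvegfr1_bound"] <- p[["k_on_mvegfr1"]] * x[["mvegfr1"]] * V -
      p[["k_off_mvegfr1"]] * x[["mvegfr1_bound"]] -
      p[["k_deg_receptor"]] * x[["mvegfr1_bound"]]
    dY[i, "svegfr1_internal"] <- p[["k_tl_svegfr1"]] * x[["svegfr1_mRNA"]] -
      p[["k_deg_receptor"]] * x[["svegfr1_internal"]] -
      p[["k_export_svegfr1"]] * x[["svegfr1_internal"]]
    dY[i, "vegfr2_mRNA"] <- v_r2 - p[["k_deg_vegfr2_mrna"]] * x[["vegfr2_mRNA"]]
    dY[i, "vegfr2"] <- p[["k_tl_vegfr2"]] * x[["vegfr2_mRNA"]] -
      p[["k_deg_receptor"]] * x[["vegfr2"]] -
      p[["k_on_vegfr2"]] * x[["vegfr2"]] * V +
      p[["k_act_decay"]] * x[["vegfr2_active"]]
    dY[i, "vegfr2_bound"] <- p[["k_on_vegfr2"]] * x[["vegfr2"]] * V -
      p[["k_off_vegfr2"]] * x[["vegfr2_bound"]] -
      p[["k_deg_receptor"]] * x[["vegfr2_bound"]]
    dY[i, "vegfr2_active"] <- p[["k_off_vegfr2"]] * x[["vegfr2_bound"]] -
      p[["k_act_decay"]] * x[["vegfr2_active"]] -
      p[["k_deg_receptor"]] * x[["vegfr2_active"]]
  }
  list(as.numeric(t(dY)))
}

oracle_run <- function(model, n = 1, neighbors = NULL, vegf_bath = 0,
                       t_end = 200, states = NULL, params = NULL, dt_out = 1) {
  if (is.null(neighbors)) neighbors <- rep(list(integer(0)), n)
  x0 <- angiosprout:::model_initial_state(model)[ode_species]
  if (is.null(states)) states <- matrix(rep(x0, each = n), nrow = n,
                                        dimnames = list(NULL, ode_species))
  if (is.null(params)) params <- lapply(seq_len(n), function(i) model$params)
  y0 <- as.numeric(t(states))
  out <- deSolve::ode(y0, seq(0, t_end, by = dt_out), oracle_rhs,
                      parms = list(P = params, neighbors = neighbors,
                                   vegf_bath = vegf_bath),
                      method = "lsoda")
  out
}

final_states <- function(out, n) {
  y <- out[nrow(out), -1]
  matrix(y, nrow = n, byrow = TRUE, dimnames = list(NULL, ode_species))
}
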