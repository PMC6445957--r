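#' The packaged intracellular endothelial-cell signaling model
#'
#' Builds the default single-cell signaling network used by every simulation:
#' Dll4-Notch1 lateral inhibition with cis-inhibition and notch1
#' auto-activation, NICD-controlled transcription of the VEGF receptors, two
#' VEGFR1 splice isoforms (membrane-bound and soluble/exported), and VEGFR2
#' activation by extracellular VEGF-A. The roster comprises 21 variables and
#' 43 intracellular parameters; all amounts are particle numbers per cell and
#' all rates are per hour.
#'
#' Species fall into three groups:
#' * 16 intracellular species integrated by the cell's ODE system
#'   (mRNAs, free receptors/ligands, complexes, NICD);
#' * 4 environment slots (`vegf_ext`, `svegfr1_ext`, `svegfr1b_ext`,
#'   `dll4_nb`) that mirror the local extracellular fields and the Dll4
#'   presented by neighboring cells — they are read and written by the cell's
#'   reactions but owned by the lattice;
#' * `filopodia`, an agent variable updated by a protrusion rule rather than a
#'   reaction (see [update_filopodia()]).
#'
#' Rate laws are restricted to three kinds: `hill_activation` (Hill kinetics
#' with basal activity, see [hill_transcription()]; two activators compose
#' multiplicatively), `hill_repression` (the mirrored decreasing form) and
#' `mass_action`.
#'
#' @param params Optional named numeric vector overriding any subset of the 43
#'   packaged parameter values.
#' @param initial Optional named numeric vector overriding initial amounts.
#' @return An object of class `ec_model`: a list with elements `species`
#'   (character), `env_species`, `rule_species`, `params` (named numeric),
#'   `initial` (named numeric over the 17 non-environment variables) and
#'   `reactions` (list of reaction descriptors).
#' @examples
#' m <- ec_model()
#' length(m$species)   # 21
#' length(m$params)    # 43
#' @export
ec_model <- function(params = NULL, initial = NULL) {
  species <- c(
    "notch1_mRNA", "notch1", "dll4_mRNA", "dll4", "nicd", "cis_complex",
    "trans_complex", "vegfr1_mRNA", "svegfr1_mRNA", "mvegfr1",
    "mvegfr1_bound", "svegfr1_internal", "vegfr2_mRNA", "vegfr2",
    "vegfr2_bound", "vegfr2_active", "vegf_ext", "svegfr1_ext",
    "svegfr1b_ext", "dll4_nb", "filopodia"
  )
  env_species <- c("vegf_ext", "svegfr1_ext", "svegfr1b_ext", "dll4_nb")
  rule_species <- "filopodia"

  p <- c(
    # transcription (Hill): maximal rates, fold activations, half-activation
    vmax_tc_notch1 = 16,  a_notch1_nicd = 4,   m0_notch1_nicd = 250,
    a_notch1_auto = 2,    m0_notch1_auto = 1500,
    vmax_tc_dll4 = 60,    a_dll4_vegfr2 = 100, m0_dll4_vegfr2 = 350,
    vmax_tc_vegfr1 = 44,  a_vegfr1_nicd = 12,  m0_vegfr1_nicd = 250,
    vmax_tc_svegfr1 = 44, a_svegfr1_nicd = 12, m0_svegfr1_nicd = 250,
    vmax_tc_vegfr2 = 40,  a_vegfr2_nicd = 30,  m0_vegfr2_nicd = 250,
    hill_h = 2,
    # translation (per mRNA per hour)
    k_tl_notch1 = 12, k_tl_dll4 = 2.4, k_tl_mvegfr1 = 20,
    k_tl_svegfr1 = 20, k_tl_vegfr2 = 2,
    # binding / conversion kinetics
    kc = 4e-5, kt = 4e-4, k_nicd_release = 2,
    k_on_mvegfr1 = 1e-4, k_off_mvegfr1 = 0.05,
    k_on_svegfr1 = 2e-4, k_off_svegfr1 = 0.05,
    k_on_vegfr2 = 2e-6,  k_off_vegfr2 = 0.5,
    k_act_decay = 1, k_export_svegfr1 = 0.5,
    # degradation
    k_deg_notch1_mrna = 0.2, k_deg_dll4_mrna = 0.2,
    k_deg_vegfr1_mrna = 0.2, k_deg_vegfr2_mrna = 0.2,
    k_deg_notch1 = 0.1, k_deg_dll4 = 0.15,
    k_nicd_degradation = 0.35, k_deg_cis = 0.2, k_deg_receptor = 0.12
  )
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(params)] <- params
  }
  if (any(p < 0)) stop("all rate parameters must be >= 0", call. = FALSE)

  x0 <- c(
    notch1_mRNA = 40, notch1 = 2000, dll4_mRNA = 60, dll4 = 2000,
    nicd = 300, cis_complex = 500, trans_complex = 50,
    vegfr1_mRNA = 100, svegfr1_mRNA = 100, mvegfr1 = 4000,
    mvegfr1_bound = 0, svegfr1_internal = 500,
    vegfr2_mRNA = 60, vegfr2 = 1000, vegfr2_bound = 0, vegfr2_active = 0,
    filopodia = 0
  )
  if (!is.null(initial)) {
    bad <- setdiff(names(initial), names(x0))
    if (length(bad)) stop("unknown initial value(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    x0[names(initial)] <- initial
  }

  hill <- function(name, law, vmax, a, m0, mod, product,
                   a2 = NULL, m02 = NULL, mod2 = NULL) {
    r <- list(name = name, law = law,
              params = c(vmax = vmax, a = a, m0 = m0, h = "hill_h"),
              modifiers = list(mod = mod), stoich = stats::setNames(1, product))
    if (!is.null(a2)) {
      r$params <- c(r$params, a2 = a2, m02 = m02)
      r$modifiers$mod2 <- mod2
    }
    r
  }
  ma <- function(name, k, rate_species, stoich) {
    list(name = name, law = "mass_action", params = c(k = k),
         rate_species = rate_species, stoich = stoich)
  }
  deg <- function(sp, k) ma(paste0("deg_", sp), k, sp, stats::setNames(-1, sp))

  reactions <- list(
    hill("tc_notch1", "hill_activation", "vmax_tc_notch1",
         "a_notch1_nicd", "m0_notch1_nicd", "nicd", "notch1_mRNA",
         a2 = "a_notch1_auto", m02 = "m0_notch1_auto", mod2 = "notch1"),
    hill("tc_dll4", "hill_activation", "vmax_tc_dll4",
         "a_dll4_vegfr2", "m0_dll4_vegfr2",
         c("vegfr2_bound", "vegfr2_active"), "dll4_mRNA"),
    hill("tc_vegfr1", "hill_activation", "vmax_tc_vegfr1",
         "a_vegfr1_nicd", "m0_vegfr1_nicd", "nicd", "vegfr1_mRNA"),
    hill("tc_svegfr1", "hill_activation", "vmax_tc_svegfr1",
         "a_svegfr1_nicd", "m0_svegfr1_nicd", "nicd", "svegfr1_mRNA"),
    hill("tc_vegfr2", "hill_repression", "vmax_tc_vegfr2",
         "a_vegfr2_nicd", "m0_vegfr2_nicd", "nicd", "vegfr2_mRNA"),
    ma("tl_notch1", "k_tl_notch1", "notch1_mRNA", c(notch1 = 1)),
    ma("tl_dll4", "k_tl_dll4", "dll4_mRNA", c(dll4 = 1)),
    ma("tl_mvegfr1", "k_tl_mvegfr1", "vegfr1_mRNA", c(mvegfr1 = 1)),
    ma("tl_svegfr1", "k_tl_svegfr1", "svegfr1_mRNA", c(svegfr1_internal = 1)),
    ma("tl_vegfr2", "k_tl_vegfr2", "vegfr2_mRNA", c(vegfr2 = 1)),
    ma("trans_bind", "kt", c("notch1", "dll4_nb"),
       c(notch1 = -1, dll4_nb = -1, trans_complex = 1)),
    ma("nicd_release", "k_nicd_release", "trans_complex",
       c(trans_complex = -1, nicd = 1)),
    ma("cis_bind", "kc", c("notch1", "dll4"),
       c(notch1 = -1, dll4 = -1, cis_complex = 1)),
    ma("mvegfr1_bind", "k_on_mvegfr1", c("mvegfr1", "vegf_ext"),
       c(mvegfr1 = -1, vegf_ext = -1, mvegfr1_bound = 1)),
    ma("mvegfr1_unbind", "k_off_mvegfr1", "mvegfr1_bound",
       c(mvegfr1_bound = -1, mvegfr1 = 1, vegf_ext = 1)),
    ma("vegfr2_bind", "k_on_vegfr2", c("vegfr2", "vegf_ext"),
       c(vegfr2 = -1, vegf_ext = -1, vegfr2_bound = 1)),
    ma("vegfr2_unbind_activate", "k_off_vegfr2", "vegfr2_bound",
       c(vegfr2_bound = -1, vegfr2_active = 1, vegf_ext = 1)),
    ma("vegfr2_active_decay", "k_act_decay", "vegfr2_active",
       c(vegfr2_active = -1, vegfr2 = 1)),
    ma("svegfr1_export", "k_export_svegfr1", "svegfr1_internal",
       c(svegfr1_internal = -1, svegfr1_ext = 1)),
    deg("notch1_mRNA", "k_deg_notch1_mrna"),
    deg("dll4_mRNA", "k_deg_dll4_mrna"),
    deg("vegfr1_mRNA", "k_deg_vegfr1_mrna"),
    deg("svegfr1_mRNA", "k_deg_vegfr1_mrna"),
    deg("vegfr2_mRNA", "k_deg_vegfr2_mrna"),
    deg("notch1", "k_deg_notch1"),
    deg("dll4", "k_deg_dll4"),
    deg("nicd", "k_nicd_degradation"),
    deg("cis_complex", "k_deg_cis"),
    deg("mvegfr1", "k_deg_receptor"),
    deg("mvegfr1_bound", "k_deg_receptor"),
    deg("svegfr1_internal", "k_deg_receptor"),
    deg("vegfr2", "k_deg_receptor"),
    deg("vegfr2_bound", "k_deg_receptor"),
    deg("vegfr2_active", "k_deg_receptor")
  )

  m <- structure(list(
    species = species, env_species = env_species, rule_species = rule_species,
    params = p, initial = x0, reactions = reactions,
    format_version = 1L
  ), class = "ec_model")
  validate_model(m)
  m
}

#' @export
print.ec_model <- function(x, ...) {
  cat("<ec_model> intracellular signaling model\n")
  cat(sprintf("  %d species (%d environment slots, %d rule variables)\n",
              length(x$species), length(x$env_species), length(x$rule_species)))
  cat(sprintf("  %d parameters, %d reactions\n",
              length(x$params), length(x$reactions)))
  invisible(x)
}

#' Validate the structure of a signaling model
#'
#' Checks species uniqueness, that every reaction references known parameters
#' and species, that rate-law kinds are among the three supported kinds, and
#' that all parameter values are finite and non-negative. Called by
#' [ec_model()] and [load_model()].
#'
#' @param m An `ec_model` object.
#' @return `m`, invisibly. Errors describe the offending entry.
#' @export
validate_model <- function(m) {
  if (!inherits(m, "ec_model")) stop("not an ec_model", call. = FALSE)
  if (anyDuplicated(m$species)) stop("duplicate species names", call. = FALSE)
  if (length(m$species) == 0L) stop("model declares no species", call. = FALSE)
  if (!all(m$env_species %in% m$species) ||
      !all(m$rule_species %in% m$species)) {
    stop("env/rule species must be declared species", call. = FALSE)
  }
  ode_species <- setdiff(m$species, m$rule_species)
  if (!all(names(m$initial) %in% setdiff(m$species, m$env_species))) {
    stop("initial values must name non-environment species", call. = FALSE)
  }
  if (any(!is.finite(m$params)) || any(m$params < 0)) {
    stop("parameters must be finite and >= 0", call. = FALSE)
  }
  laws <- c("hill_activation", "hill_repression", "mass_action")
  for (r in m$reactions) {
    if (!r$law %in% laws) {
      stop(sprintf("reaction '%s': unknown rate law '%s'", r$name, r$law),
           call. = FALSE)
    }
    miss <- setdiff(unname(r$params), names(m$params))
    if (length(miss)) {
      stop(sprintf("reaction '%s': unknown parameter(s) %s", r$name,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    sp <- names(r$stoich)
    if (r$law == "mass_action") sp <- c(sp, r$rate_species)
    if (r$law != "mass_action") sp <- c(sp, unlist(r$modifiers))
    miss <- setdiff(sp, ode_species)
    if (length(miss)) {
      stop(sprintf("reaction '%s': unknown species %s", r$name,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(m)
}

# Integer-encoded form consumed by the C++ kernels. Indices are 0-based.
model_compile <- function(m) {
  validate_model(m)
  sp_idx <- function(s) match(s, m$species) - 1L
  pr_idx <- function(s) match(s, names(m$params)) - 1L
  law_code <- c(hill_activation = 0L, hill_repression = 1L, mass_action = 2L)
  rx <- lapply(m$reactions, function(r) {
    out <- list(law = law_code[[r$law]],
                stoich_idx = sp_idx(names(r$stoich)),
                stoich_coef = as.numeric(r$stoich))
    if (r$law == "mass_action") {
      out$pidx <- pr_idx(r$params[["k"]])
      out$rate_idx <- sp_idx(r$rate_species)
    } else {
      out$pidx <- pr_idx(r$params[c("vmax", "a", "m0", "h")])
      out$mod_idx <- sp_idx(r$modifiers$mod)
      if (!is.null(r$modifiers$mod2)) {
        out$pidx2 <- pr_idx(r$params[c("a2", "m02")])
        out$mod2_idx <- sp_idx(r$modifiers$mod2)
      } else {
        out$pidx2 <- integer(0)
        out$mod2_idx <- integer(0)
      }
    }
    out
  })
  list(
    n_species = length(m$species),
    n_params = length(m$params),
    reactions = rx,
    env_idx = sp_idx(m$env_species),
    rule_idx = sp_idx(m$rule_species),
    species = m$species,
    param_names = names(m$params),
    reaction_names = vapply(m$reactions, `[[`, "", "name")
  )
}

# Full-length state vector (all species) from the model's initial values;
# environment slots start at 0 and are refreshed by the engine.
model_initial_state <- function(m) {
  x <- stats::setNames(numeric(length(m$species)), m$species)
  x[names(m$initial)] <- m$initial
  x
}
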