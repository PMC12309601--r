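#' The canonical copper-trafficking reaction network
#'
#' Builds the 10-component, 25-reaction network describing cytosolic copper
#' trafficking in a growing yeast cell. Components are the apo and holo forms
#' of the MAC and ACE transcription factors, the CUP metallothionein and the
#' collective OTH pool of other copper proteins, plus the CTR importer protein
#' and the labile copper pool CU. Reactions comprise five biosynthesis steps
#' (`BAMAC`, `BAACE`, `BACUP`, `BAOTH`, `BCTR`), two nutrient-copper imports
#' (`CUIN1`, catalyzed by CTR with Michaelis constant 2 uM; `CUIN2`, with
#' Michaelis constant 35 uM), four reversible metallation pairs
#' (`MMACF`/`MMACR`, `MACEF`/`MACER`, `MCUPF`/`MCUPR`, `MOTHF`/`MOTHR`,
#' consuming 4, 4, 8 and 1 CU respectively) and one growth-dilution reaction
#' per component.
#'
#' Four reactions carry a logistic (soft Heaviside) regulation flag: `BACUP`,
#' `MCUPF` and `MOTHF` sense the labile pool CU, while `CUIN2` senses the
#' nutrient COPPER concentration. Metallation rate laws carry the cooperativity
#' exponents fitted from the transcription-factor titrations (0.62 for MAC,
#' 0.90 for ACE, 1.1 for CUP); OTH metallation is noncooperative (exponent 1)
#' by default.
#'
#' @param oth_exponent Cooperativity exponent used in the OTH metallation rate
#'   law. Defaults to 1 (noncooperative).
#' @return An object of class `cu_network`: a list with tibbles `components`
#'   and `reactions`.
#' @examples
#' net <- build_canonical_network()
#' nrow(net$reactions) # 25
#' @export
build_canonical_network <- function(oth_exponent = 1) {
  components <- tibble::tibble(
    name = c("aMAC", "MAC", "aACE", "ACE", "aCUP", "CUP",
             "aOTH", "OTH", "CTR", "CU"),
    role = c("regulating", "regulating", "regulating", "regulating",
             "regulating", "regulating", "regulated", "regulated",
             "regulating", "regulated"),
    cu_stoich = c(0L, 4L, 0L, 4L, 0L, 8L, 0L, 1L, 0L, 1L)
  )

  rx <- function(name, class, substrates = list(), products = list(),
                 catalyst = NA_character_, km = NA_real_, exponent = NA_real_,
                 logistic_sensor = NA_character_) {
    tibble::tibble(
      name = name, class = class,
      substrates = list(substrates), products = list(products),
      catalyst = catalyst, km = km, exponent = exponent,
      logistic_sensor = logistic_sensor
    )
  }

  reactions <- dplyr::bind_rows(
    rx("BAMAC", "constant_biosynthesis", products = list(aMAC = 1L)),
    rx("BAACE", "constant_biosynthesis", products = list(aACE = 1L)),
    rx("BACUP", "catalyzed_biosynthesis", products = list(aCUP = 1L),
       catalyst = "ACE", logistic_sensor = "CU"),
    rx("BAOTH", "constant_biosynthesis", products = list(aOTH = 1L)),
    rx("BCTR", "catalyzed_biosynthesis", products = list(CTR = 1L),
       catalyst = "aMAC"),
    rx("CUIN1", "michaelis_menten_import", products = list(CU = 1L),
       catalyst = "CTR", km = 2),
    rx("CUIN2", "michaelis_menten_import", products = list(CU = 1L),
       km = 35, logistic_sensor = "COPPER"),
    rx("MMACF", "mass_action_metallation",
       substrates = list(aMAC = 1L, CU = 4L), products = list(MAC = 1L),
       exponent = 0.62),
    rx("MACEF", "mass_action_metallation",
       substrates = list(aACE = 1L, CU = 4L), products = list(ACE = 1L),
       exponent = 0.90),
    rx("MCUPF", "mass_action_metallation",
       substrates = list(aCUP = 1L, CU = 8L), products = list(CUP = 1L),
       exponent = 1.1, logistic_sensor = "CU"),
    rx("MOTHF", "mass_action_metallation",
       substrates = list(aOTH = 1L, CU = 1L), products = list(OTH = 1L),
       exponent = oth_exponent, logistic_sensor = "CU"),
    rx("MMACR", "first_order_demetallation",
       substrates = list(MAC = 1L), products = list(aMAC = 1L, CU = 4L)),
    rx("MACER", "first_order_demetallation",
       substrates = list(ACE = 1L), products = list(aACE = 1L, CU = 4L)),
    rx("MCUPR", "first_order_demetallation",
       substrates = list(CUP = 1L), products = list(aCUP = 1L, CU = 8L)),
    rx("MOTHR", "first_order_demetallation",
       substrates = list(OTH = 1L), products = list(aOTH = 1L, CU = 1L)),
    dplyr::bind_rows(lapply(components$name, function(cn) {
      s <- list(1L); names(s) <- cn
      rx(paste0("D", toupper(sub("^a", "A", cn))), "first_order_dilution",
         substrates = s)
    }))
  )

  net <- structure(list(components = components, reactions = reactions),
                   class = "cu_network")
  validate_network(net)
  net
}

# Dilution reaction name for a component ("aMAC" -> "DAMAC", "CU" -> "DCU").
dilution_name <- function(component) {
  paste0("D", toupper(sub("^a", "A", component)))
}

validate_network <- function(network) {
  comps <- network$components$name
  for (i in seq_len(nrow(network$reactions))) {
    r <- network$reactions[i, ]
    parts <- c(names(r$substrates[[1]]), names(r$products[[1]]))
    if (!all(parts %in% comps)) {
      rlang::abort(paste0("reaction ", r$name, " references unknown components"))
    }
  }
  invisible(network)
}

#' @export
print.cu_network <- function(x, ...) {
  cat("<cu_network> ", nrow(x$components), " components, ",
      nrow(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' Returns the components-by-reactions matrix S of signed stoichiometric
#' coefficients, so that `S %*% R` gives the vector of component concentration
#' derivatives for a reaction-rate vector `R`. For the canonical network S is
#' 10 x 25 with full row rank (the dilution block is a negated identity).
#'
#' @param network A `cu_network`.
#' @return An integer matrix with component row names and reaction column names.
#' @export
stoichiometric_matrix <- function(network) {
  comps <- network$components$name
  rxns <- network$reactions$name
  S <- matrix(0L, nrow = length(comps), ncol = length(rxns),
              dimnames = list(comps, rxns))
  for (i in seq_along(rxns)) {
    subs <- network$reactions$substrates[[i]]
    prods <- network$reactions$products[[i]]
    for (nm in names(subs)) S[nm, i] <- S[nm, i] - subs[[nm]]
    for (nm in names(prods)) S[nm, i] <- S[nm, i] + prods[[nm]]
  }
  S
}

#' Copper equivalents carried per component
#'
#' Weight vector used in copper mass balances: the holo forms of MAC, ACE, CUP
#' and OTH carry 4, 4, 8 and 1 copper ions, the labile pool CU carries 1, and
#' apo forms and CTR carry none. Total cellular copper is the dot product of
#' these weights with the component concentrations.
#'
#' @param network A `cu_network`.
#' @return A named numeric vector, one entry per component.
#' @export
cu_weight_vector <- function(network) {
  stats::setNames(as.numeric(network$components$cu_stoich),
                  network$components$name)
}

#' Reference state for rate-law normalization
#'
#' Rate laws are normalized by the steady-state concentrations of the central
#' (M10) condition, so that at the reference state every normalization factor
#' equals one and each reaction runs at its bare rate constant (times the
#' import saturation factor, and times the logistic factor where flagged).
#'
#' @param concentrations Named numeric vector of the 10 component
#'   concentrations (uM) at the reference (M10) condition; all must be > 0.
#' @param alpha Exponential growth rate of the culture, per minute.
#' @param copper_by_condition Optional named numeric vector of effective
#'   nutrient COPPER (uM) per condition label.
#' @return An object of class `cu_reference`.
#' @export
cu_reference <- function(concentrations, alpha = 0.0033,
                         copper_by_condition = NULL) {
  if (any(concentrations <= 0)) {
    rlang::abort("all reference concentrations must be positive")
  }
  structure(list(concentrations = concentrations, alpha = alpha,
                 copper_by_condition = copper_by_condition),
            class = "cu_reference")
}

# Normalized rate-law factor for every reaction, excluding the rate constant
# and any logistic augmentation. `state` is a named vector of component
# concentrations (uM), `copper` the nutrient COPPER (uM).
rate_factors <- function(network, state, copper, ref) {
  if (any(state < 0)) rlang::abort("negative component concentration")
  if (copper < 0) rlang::abort("negative COPPER concentration")
  refc <- ref$concentrations
  n_rx <- nrow(network$reactions)
  out <- stats::setNames(numeric(n_rx), network$reactions$name)
  for (i in seq_len(n_rx)) {
    r <- network$reactions[i, ]
    f <- switch(r$class,
      constant_biosynthesis = 1,
      catalyzed_biosynthesis = state[[r$catalyst]] / refc[[r$catalyst]],
      michaelis_menten_import = {
        sat <- copper / (r$km + copper)
        if (!is.na(r$catalyst)) sat * state[[r$catalyst]] / refc[[r$catalyst]] else sat
      },
      mass_action_metallation = {
        apo <- names(r$substrates[[1]])[names(r$substrates[[1]]) != "CU"]
        (state[[apo]] / refc[[apo]]) *
          (state[["CU"]] / refc[["CU"]])^r$exponent
      },
      first_order_demetallation = {
        holo <- names(r$substrates[[1]])
        state[[holo]] / refc[[holo]]
      },
      first_order_dilution = {
        cn <- names(r$substrates[[1]])
        state[[cn]] / refc[[cn]]
      },
      rlang::abort(paste0("unknown rate law class: ", r$class))
    )
    out[i] <- f
  }
  out
}

#' Evaluate the rate of one reaction
#'
#' Applies the reaction's normalized rate law at a given cellular state:
#' mass-action metallation uses the apo form times the labile pool raised to
#' its cooperativity exponent, demetallation and dilution are first order in
#' the normalized substrate, imports carry a Michaelis saturation factor in
#' COPPER, and catalyzed biosynthesis is first order in the normalized
#' catalyst. All normalizations are with respect to the reference (M10) state.
#'
#' @param network A `cu_network`.
#' @param reaction Reaction name.
#' @param k Rate constant (uM/min at the reference state).
#' @param state Named numeric vector of component concentrations (uM).
#' @param copper Nutrient COPPER concentration (uM).
#' @param ref A [cu_reference()].
#' @param logistic Optional `cu_logistic` parameters; when supplied the rate is
#'   multiplied by the logistic factor evaluated at the sensed species.
#' @return Rate in uM/min.
#' @export
evaluate_rate <- function(network, reaction, k, state, copper, ref,
                          logistic = NULL) {
  i <- match(reaction, network$reactions$name)
  if (is.na(i)) rlang::abort(paste0("unknown reaction: ", reaction))
  f <- rate_factors(network, state, copper, ref)[[reaction]]
  lf <- 1
  if (!is.null(logistic)) {
    sensor <- network$reactions$logistic_sensor[[i]]
    sen <- if (identical(sensor, "COPPER")) copper else state[["CU"]]
    lf <- logistic_factor(logistic$n_sens, logistic$sen_sp, sen)
  }
  k * f * lf
}

#' Serialize a network to YAML
#'
#' Writes (or returns) a structured text definition of the network listing
#' components, reactions, stoichiometries and rate-law parameters, suitable
#' for round-tripping with [network_from_yaml()].
#'
#' @param network A `cu_network`.
#' @param file Optional path; when `NULL` the YAML text is returned.
#' @return The YAML string, invisibly when written to a file.
#' @export
network_to_yaml <- function(network, file = NULL) {
  obj <- list(
    components = purrr::pmap(network$components, function(name, role, cu_stoich) {
      list(name = name, role = role, cu_stoich = cu_stoich)
    }),
    reactions = purrr::pmap(network$reactions, function(name, class, substrates,
                                                        products, catalyst, km,
                                                        exponent, logistic_sensor) {
      out <- list(name = name, class = class)
      if (length(substrates)) out$substrates <- substrates
      if (length(products)) out$products <- products
      if (!is.na(catalyst)) out$catalyst <- catalyst
      if (!is.na(km)) out$km <- km
      if (!is.na(exponent)) out$exponent <- exponent
      if (!is.na(logistic_sensor)) out$logistic_sensor <- logistic_sensor
      out
    })
  )
  txt <- yaml::as.yaml(obj)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a network from a YAML definition
#'
#' @param file Path to a YAML file produced by [network_to_yaml()] (or text
#'   via `text =`).
#' @param text YAML text, as an alternative to `file`.
#' @return A `cu_network`.
#' @export
network_from_yaml <- function(file = NULL, text = NULL) {
  obj <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(file)
  components <- dplyr::bind_rows(lapply(obj$components, function(cp) {
    tibble::tibble(name = cp$name, role = cp$role,
                   cu_stoich = as.integer(cp$cu_stoich))
  }))
  reactions <- dplyr::bind_rows(lapply(obj$reactions, function(r) {
    tibble::tibble(
      name = r$name, class = r$class,
      substrates = list(lapply(r$substrates %||% list(), as.integer)),
      products = list(lapply(r$products %||% list(), as.integer)),
      catalyst = r$catalyst %||% NA_character_,
      km = r$km %||% NA_real_,
      exponent = r$exponent %||% NA_real_,
      logistic_sensor = r$logistic_sensor %||% NA_character_
    )
  }))
  net <- structure(list(components = components, reactions = reactions),
                   class = "cu_network")
  validate_network(net)
  net
}
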