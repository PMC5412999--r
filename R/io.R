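# Model serialization: YAML (canonical) and JSON, schema version 1.
# Keys: schema, schema_version, temperature, pKw, geometry{surface_area,
# solids_conc}, components[], sites[], surface_reactions[] (with a
# `consumed` map), aqueous_reactions[] (with a `stoich` map).

model_to_list <- function(model) {
  sr <- model$surface_reactions
  aq <- model$aqueous_reactions
  list(
    schema = "ionex-model",
    schema_version = 1L,
    temperature = model$temperature,
    pKw = model$pKw,
    geometry = if (is.null(model$geometry)) NULL else
      list(surface_area = model$geometry$surface_area,
           solids_conc = model$geometry$solids_conc),
    components = purrr::pmap(model$components, \(name, charge)
                             list(name = name, charge = charge)),
    sites = purrr::pmap(model$sites, \(site, gamma_max)
                        list(site = site, gamma_max = gamma_max)),
    surface_reactions = purrr::map(seq_len(nrow(sr)), function(i) {
      list(id = sr$id[i], site = sr$site[i], product = sr$product[i],
           n_soh = sr$n_soh[i], scale = sr$scale[i], pK = sr$pK[i],
           tie_group = if (is.na(sr$tie_group[i])) NULL else sr$tie_group[i],
           fixed = sr$fixed[i],
           consumed = as.list(sr$consumed[[i]]))
    }),
    aqueous_reactions = purrr::map(seq_len(nrow(aq)), function(i) {
      list(species = aq$species[i], logK = aq$logK[i],
           stoich = as.list(aq$stoich[[i]]))
    })
  )
}

list_to_model <- function(x) {
  if (!identical(x$schema, "ionex-model")) {
    ionex_abort("not an ionex-model file (missing `schema: ionex-model`)",
                "ionex_schema_error")
  }
  comps <- bind_rows(purrr::map(x$components, as_tibble))
  sites <- purrr::map(x$sites, \(s) iex_site(s$site, s$gamma_max))
  scalar_or <- function(v, default) {
    if (is.null(v) || length(v) == 0) default else v
  }
  srx <- purrr::map(x$surface_reactions, function(r) {
    exchange_reaction(r$site, unlist(r$consumed), r$product, pK = r$pK,
                      n_soh = scalar_or(r$n_soh, 1), id = r$id,
                      scale = scalar_or(r$scale, 1),
                      tie_group = scalar_or(r$tie_group, NA_character_),
                      fixed = isTRUE(r$fixed))
  })
  aqx <- purrr::map(x$aqueous_reactions,
                    \(a) aqueous_reaction(a$species, unlist(a$stoich), a$logK))
  iex_model(sites, srx, aqueous_reactions = aqx, components = comps,
            geometry = if (is.null(x$geometry)) NULL else
              iex_geometry(x$geometry$surface_area, x$geometry$solids_conc),
            temperature = x$temperature %||% 293.15,
            pKw = x$pKw %||% 14)
}

#' Read / write an ion-exchange model file
#'
#' YAML is the canonical format; `.json` files use the same schema.  The
#' format is chosen from the file extension.
#'
#' @param model An [iex_model()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_model()` returns the validated `iex_model`;
#'   `write_model()` returns `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "iex_model"))
  x <- model_to_list(model)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    ionex_abort(sprintf("file not found: %s", path), "ionex_io_error")
  }
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  list_to_model(x)
}
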