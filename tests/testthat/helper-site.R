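# a bare in-memory active-site model for constructed-geometry tests
bare_site <- function(fe = c(0, 0, 0), ser_og = NULL, water623 = NULL,
                      phe_ring = NULL, heme = NULL) {
  hb <- list()
  if (!is.null(ser_og))
    hb$Ser119 <- data.frame(atom = "OG", x = ser_og[1], y = ser_og[2],
                            z = ser_og[3])
  waters <- list()
  if (!is.null(water623)) waters[["623"]] <- water623
  phe <- list()
  if (!is.null(phe_ring)) phe$Phe108 <- phe_ring
  if (is.null(heme)) heme <- matrix(fe, 1, 3, dimnames = list("FE", NULL))
  structure(list(fe_position = fe, hbond_residues = hb, waters = waters,
                 phe_cluster = phe, heme_atoms = heme,
                 provenance = character(0), source = "in-memory"),
            class = "active_site_model")
}

mol_at <- function(df, name = "probe") som_molecule(df, NULL, name,
                                                    check_hydrogens = FALSE)
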