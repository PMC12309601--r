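# Shared fixtures for the test suite, computed once per test run.
cf_net <- build_canonical_network()
cf_S <- stoichiometric_matrix(cf_net)
cf_conds <- assemble_condition_table()
cf_ref <- reference_from_conditions(cf_conds)
cf_rate_table <- suppressWarnings(steady_state_rate_table(cf_conds, cf_net, cf_ref))
cf_kt <- apparent_rate_constants(cf_rate_table, cf_conds, cf_net, cf_ref)
cf_cls <- classify_invariance(cf_kt)
cf_params <- consolidate_constants(cf_cls, cf_conds)
cf_comp <- c("aMAC", "MAC", "aACE", "ACE", "aCUP", "CUP",
             "aOTH", "OTH", "CTR", "CU")
cf_m10_state <- unlist(cf_conds[cf_conds$condition == "M10", cf_comp])

# Small two-component flow network with a known extreme-ray decomposition:
# in_A (-> A), conv (A -> B), out_B (B ->), out_A (A ->), in_B (-> B),
# exch (B -> A). Five extreme rays: in_A/out_A, in_A/conv/out_B, in_B/out_B,
# in_B/exch/out_A, and the conv+exch cycle.
mini_S <- matrix(c(
  1, -1,  0, -1,  0,  1,
  0,  1, -1,  0,  1, -1
), nrow = 2, byrow = TRUE,
dimnames = list(c("A", "B"),
                c("in_A", "conv", "out_B", "out_A", "in_B", "exch")))
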