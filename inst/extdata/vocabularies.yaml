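# Controlled vocabularies for occurrence metadata.
# Cardinalities follow the conventional scheme (8 taphonomic modes, 17
# paleoenvironments ordered shallow -> deep, 33 body morphogroups, 24 trace
# architectural groups, 22 lumped form categories). Labels are representative
# defaults; projects with their own supplementary vocabulary should point
# load_vocabularies() at an equivalent file.
preservational_modes:
  - cast_mold                 # Ediacara-type casts, molds, impressions
  - carbonaceous_compression
  - skeletal
  - secondarily_mineralized_tube
  - agglutinated
  - trace
  - permineralized
  - other_mode
environments:                 # ordered from shallowest to deepest
  - tidal_flat
  - lagoon
  - upper_shoreface
  - lower_shoreface
  - offshore_transition
  - offshore_shelf
  - inner_ramp
  - mid_ramp
  - outer_ramp
  - carbonate_platform
  - reef_margin
  - delta_front
  - prodelta
  - slope_turbiditic
  - carbonate_slope_basin
  - basin_plain
  - deep_basin_turbiditic
morphogroups:
  - rangeomorph
  - arboreomorph
  - dickinsoniomorph
  - bilateralomorph
  - kimberellomorph
  - triradialomorph
  - tetraradialomorph
  - pentaradialomorph
  - octoradialomorph
  - frondomorph
  - palaeopascichnid
  - tubular_annulated
  - tubular_smooth
  - cloudinomorph
  - namacalathid
  - sabelliditid
  - vendotaenid
  - filamentous_compression
  - strap_shaped_compression
  - ribbon_shaped_compression
  - globular_compression
  - dendritic_compression
  - sponge_like
  - cnidarian_like
  - mollusc_like
  - annelid_like
  - erniettomorph
  - pteridiniomorph
  - aspidellomorph
  - agglutinated_test
  - spheroidal
  - conical
  - problematic_body
trace_architectures:
  - simple_horizontal_trail
  - sinuous_horizontal_trail
  - meandering_trail
  - looping_trail
  - horizontal_branching_burrow
  - vertical_burrow
  - u_shaped_burrow
  - plug_shaped_burrow
  - horizontal_burrow_lined
  - horizontal_burrow_unlined
  - treptichnid_burrow
  - probe_like_burrow
  - radial_trace
  - rosette_trace
  - star_shaped_trace
  - scratch_array
  - resting_trace
  - locomotion_trace
  - grazing_trace
  - feeding_excavation
  - fecal_string
  - imbricated_backfill
  - spiral_burrow
  - network_burrow
form_categories:
  - frond
  - disc
  - tube
  - shell
  - vase
  - sphere
  - cone
  - filament
  - strap
  - ribbon
  - segmented_body
  - radial_body
  - bilateral_body
  - modular_body
  - encrusting_body
  - test
  - trail
  - burrow
  - radial_trace_form
  - resting_form
  - complex_trace_form
  - problematic_form
flags:
  - disc_shaped
  - possible_taphomorph
  - possible_pseudofossil
  - possible_synonym
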