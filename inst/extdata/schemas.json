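{
  "dialect": {
    "format": "TSV, UTF-8, header row, '.' decimal separator, empty string = missing",
    "depth_convention": "centimeters below sediment surface; intervals half-open [top, bottom); midpoint used where one depth per sample is needed"
  },
  "mag_catalog": {
    "columns": {
      "mag_id": "string, unique key",
      "taxonomy": "7-rank semicolon-delimited lineage (GTDB-style prefixes accepted and stripped)",
      "completeness": "percent, 75-100 after quality filter",
      "redundancy": "percent, [0, 10) after quality filter",
      "genome_size": "optional, basepairs > 0"
    }
  },
  "gene_table": {
    "columns": {
      "mag_id": "string, in mag_catalog",
      "feature_id": "KEGG ortholog id or gene symbol",
      "copies": "integer >= 1"
    },
    "key": ["mag_id", "feature_id"]
  },
  "metal_flag_table": {
    "columns": {
      "mag_id": "string, in mag_catalog",
      "porin_cytochrome_homolog": "boolean (FeGenie-style porin-cytochrome homolog present)"
    }
  },
  "cazyme_table": {
    "columns": {
      "mag_id": "string, in mag_catalog",
      "cazyme_family": "label matching ^(GH|PL|CBM|GT|CE|AA)[0-9]+$",
      "copies": "integer >= 1",
      "secreted_copies": "integer in [0, copies] (SignalP-positive copies)"
    },
    "key": ["mag_id", "cazyme_family"]
  },
  "coverage_matrix": {
    "layout": "wide: first column mag_id, one numeric column per sample_id; values finite and >= 0"
  },
  "sample_metadata": {
    "columns": {
      "sample_id": "string, unique key",
      "site_id": "string",
      "depth_top_cm": ">= 0",
      "depth_bottom_cm": "> depth_top_cm; intervals within a site non-overlapping",
      "water_depth_m": "> 0",
      "o2_penetration_cm": "> 0",
      "no3_penetration_cm": "> o2_penetration_cm",
      "sedimentation_rate_mm_yr": "> 0; warning outside 0.01-10",
      "zone": "optional derived enum: oxic | nitrogenous | ferruginous (| transitional)"
    }
  },
  "module_definitions": {
    "columns": {
      "module_id": "string",
      "step_index": "integer >= 1, ordered within module",
      "features": "comma-joined alternative feature ids for the step (non-empty)"
    }
  },
  "guild_assignment": {
    "columns": {
      "mag_id": "string",
      "oxidase and nitrogen step flags": "boolean sub-flags (has_cytc_oxidase, has_cbb3, has_bd, taxon_override_aerobic, napAB, narGHI, nrfAH, nirBD, nirKS, norBC, nosZ, full_denitrifier, dsrAB)",
      "aerobic|nitrogen|sulfur_resp|metal_resp|fermenter": "derived capabilities; fermenter = none of the other four"
    }
  }
}
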