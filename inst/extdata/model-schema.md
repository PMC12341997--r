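# gemctx JSON model dialect

A single JSON object with four members. `write_model(..., format = "json")`
and `read_model()` round-trip this format exactly.

```json
{
  "id": "model-name",
  "metabolites": [
    {
      "id": "glc_c",            // unique, required
      "name": "D-glucose",      // optional, defaults to id
      "compartment": "c",       // one of c,e,g,i,l,m,n,r,x; required
      "formula": "C6H12O6",     // flat elemental formula, "" if unknown
      "charge": 0               // integer; omitted if unset
    }
  ],
  "reactions": [
    {
      "id": "HEX1",             // unique, required
      "name": "hexokinase",     // optional
      "stoichiometry": {        // metabolite id -> signed coefficient,
        "glc_c": -1,            // negative = substrate
        "atp_c": -1,
        "g6p_c": 1,
        "adp_c": 1
      },
      "lower_bound": 0,         // mmol gDW^-1 h^-1; required
      "upper_bound": 1000,      // required
      "gpr": "HK1 or HK2",      // boolean rule string; "" for none
      "subsystem": "glycolysis" // free text
    }
  ],
  "objective": {                // null if no objective
    "reaction": "BIOMASS",
    "sense": "maximize"         // only maximize is supported
  }
}
```

Conventions:

* Exchange reactions are single-metabolite boundary reactions written as
  `"M ->"` (`stoichiometry: {"M": -1}`); uptake is negative flux.
* GPR rule grammar: gene tokens are any non-whitespace run excluding
  parentheses; `and` binds tighter than `or`; keywords are
  case-insensitive.
* Every metabolite referenced by a reaction must appear in `metabolites`;
  duplicate ids and missing bounds are validation errors on read.
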