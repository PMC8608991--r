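# DBS lead geometry registry (mm). version 1
# tip_to_first_contact is the offset of the first contact CENTRE from the tip:
# a 1.5 mm distal contact flush with the tip has its centre at 0.75 mm.
version: 1
leads:
  medtronic3389:
    n_contacts: 4
    contact_length: 1.5
    intercontact_gap: 0.5
    tip_to_first_contact: 0.75
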