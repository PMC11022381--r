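sample_id	arms_unit	locality	ph_level	fraction	species
east_control_u1_h	east_control_u1	east	control	benthic_holobiont	NA
east_control_u1_s	east_control_u1	east	control	sediment	NA
east_control_u2_h	east_control_u2	east	control	benthic_holobiont	NA
east_control_u2_s	east_control_u2	east	control	sediment	NA
east_control_u3_h	east_control_u3	east	control	benthic_holobiont	NA
east_control_u3_s	east_control_u3	east	control	sediment	NA
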