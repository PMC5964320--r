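"task_id","comp09","comp08","comp05","comp06"
"tower_of_london",0.85,0.25,0.4,0.35
"deductive_reasoning",0.82,0.32,0.45,0.3
"wisconsin_card_sorting",0.8,0.45,0.5,0.4
"counting_calculation",0.7,0.4,0.55,0.35
"n_back",0.65,0.5,0.5,0.45
"mental_rotation",0.6,0.35,0.3,0.4
"encoding",0.55,0.3,0.35,0.3
"visual_search",0.5,0.4,0.3,0.35
"spatial_attention",0.5,0.45,0.35,0.4
"semantic_judgment",0.45,0.5,0.4,0.3
"word_generation",0.4,0.45,0.5,0.35
"reading",0.3,0.5,0.4,0.3
"divided_auditory_attention",0.25,0.55,0.45,0.4
"imagined_movement",0.2,0.65,0.4,0.45
"go_no_go",0.2,0.7,0.5,0.45
"passive_listening",0.15,0.6,0.35,0.3
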