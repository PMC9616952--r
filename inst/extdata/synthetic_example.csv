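record_id,study_id,research_group_id,species,genus,family,order,n_caught,n_dead,ocean,hook_shape,hook_type,hooks_between_floats,soak_duration,bait_type,body_form,ventilation_mode
r1,stA,gA,Synthus sp01,Synthus,Synthidae,Synthiformes,20,5,Atlantic,circle,tuna,25,10.5,squid,fusiform,ram_obligate
r2,stA,gA,Synthus sp01,Synthus,Synthidae,Synthiformes,15,3,Atlantic,J,tuna,25,9.0,fish,fusiform,ram_obligate
r3,stB,gA,Synthus sp02,Synthus,Synthidae,Synthiformes,30,12,Pacific,circle,tuna,18,,squid,fusiform,ram_obligate
r4,stB,gA,Synthus sp02,Synthus,Synthidae,Synthiformes,10,0,Pacific,J,,18,12.0,mixed,fusiform,ram_obligate
r5,stC,gB,Parasynthus sp03,Parasynthus,Parasynthidae,Parasynthiformes,25,20,Atlantic,circle,swordfish,,8.5,fish,dorsoventrally_flattened,buccal_facultative
r6,stC,gB,Parasynthus sp03,Parasynthus,Parasynthidae,Parasynthiformes,40,35,Mediterranean,J,swordfish,30,11.0,squid,dorsoventrally_flattened,buccal_facultative
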