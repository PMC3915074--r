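CATEGORY,ELEMENT,ATTRIBUTE,RECOMMENDED,DERIVED,HAS_UNIT,MEAN_SCORE
authorship,Author,author_name,true,false,false,4.5
authorship,Author,institution,false,false,false,3.6
authorship,Author,contact_email,false,false,false,3.2
authorship,Citation,citation_identifier,true,false,false,4.3
authorship,Grant,funding_agency,false,false,false,2.9
authorship,Grant,grant_number,false,false,false,2.7
platform,Software,software_name,true,false,false,4.8
platform,Software,software_version,true,false,false,4.6
platform,Software,executable_name,false,false,false,3.8
platform,ComputingEnvironment,operating_system,false,false,false,3.1
platform,ComputingEnvironment,cpu_architecture,true,false,false,4.1
platform,ComputingEnvironment,gpu_architecture,false,false,false,3.9
platform,ComputingEnvironment,machine_architecture,false,false,false,3.4
platform,ComputingEnvironment,machine_name,false,false,false,2.8
platform,TaskExecution,start_time,false,false,false,3.0
platform,TaskExecution,end_time,false,false,false,3.0
platform,TaskExecution,elapsed_time,false,false,true,3.5
platform,TaskExecution,termination_status,false,false,false,4.0
platform,FileSystem,file_system_type,false,false,false,2.6
platform,FileSystem,file_system_host,false,false,false,2.5
platform,File,file_format,true,false,false,4.7
platform,File,file_size,false,false,true,3.7
platform,File,file_role,true,false,false,4.2
molecular system,MolecularSystem,system_name,true,false,false,4.4
molecular system,ReferenceStructure,structure_database,false,false,false,3.9
molecular system,ReferenceStructure,structure_entry_id,true,false,false,4.5
molecular system,ResidueSequence,specific_chain,false,false,false,3.8
molecular system,ResidueSequence,normalized_chain,true,false,false,4.3
methods,ExperimentTask,method_name,true,false,false,4.9
methods,ExperimentTask,boundary_conditions,true,false,false,4.2
methods,ExperimentTask,solvent_type,true,false,false,4.6
methods,SimulatedConditions,reference_temperature,true,false,true,4.7
methods,SimulatedConditions,reference_pressure,false,false,true,3.9
molecules,Molecule,molecule_name,true,false,false,4.4
molecules,Molecule,molecule_count,false,false,false,3.8
molecules,Biomolecule,biomolecule_type,true,false,false,4.6
molecules,Biomolecule,species,false,false,false,3.6
molecules,ResidueOccurrence,residue_name,true,false,false,4.1
molecules,AtomOccurrence,element_symbol,true,false,false,4.2
molecular dynamics,MDParameterSet,number_of_steps,true,false,false,4.5
molecular dynamics,MDParameterSet,step_length,true,false,true,4.6
molecular dynamics,MDParameterSet,run_context,true,false,false,4.4
molecular dynamics,MDParameterSet,collision_frequency,false,false,true,3.0
molecular dynamics,ForceField,force_field_name,true,false,false,4.8
molecular dynamics,ForceField,force_field_type,false,true,false,
molecular dynamics,ForceField,coarse_grain_flag,false,false,false,3.3
molecular dynamics,Barostat,barostat_implementation,true,false,false,4.1
molecular dynamics,Barostat,barostat_time_constant,false,false,true,3.2
molecular dynamics,Barostat,barostat_chain_length,false,false,false,2.8
molecular dynamics,Thermostat,thermostat_implementation,true,false,false,4.3
molecular dynamics,Thermostat,thermostat_time_constant,false,false,true,3.3
molecular dynamics,Thermostat,thermostat_chain_length,false,false,false,2.9
molecular dynamics,Ensemble,ensemble_type,true,false,false,4.5
molecular dynamics,Constraint,constraint_algorithm,true,false,false,4.2
molecular dynamics,Constraint,constraint_target,false,false,false,3.7
molecular dynamics,Restraint,restrained_property,false,false,false,3.9
molecular dynamics,Restraint,restraint_target,false,false,false,3.6
molecular dynamics,Electrostatics,electrostatics_model,true,false,false,4.4
molecular dynamics,EnhancedSampling,enhanced_sampling_method,true,false,false,4.3
molecular dynamics,EnhancedSampling,replica_count,false,false,false,3.8
quantum mechanics,QMMethod,qm_method_name,true,false,false,4.7
quantum mechanics,QMMethod,qm_method_class,false,true,false,
quantum mechanics,QMMethod,qm_method_family,false,true,false,
quantum mechanics,BasisSet,basis_set_name,true,false,false,4.6
quantum mechanics,BasisSet,basis_set_type,false,true,false,
quantum mechanics,QMApproximations,frozen_core_flag,false,false,false,3.4
quantum mechanics,QMApproximations,pseudopotentials_flag,false,false,false,3.5
quantum mechanics,QMApproximations,plane_wave_cutoff,false,false,true,3.6
quantum mechanics,Convergence,convergence_flag,false,false,false,3.8
quantum mechanics,Convergence,convergence_criteria,false,false,false,3.7
quantum mechanics,ExchangeCorrelationFunctional,functional_name,false,false,false,4.0
quantum mechanics,QMMMBoundary,boundary_treatment,false,false,false,3.9
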